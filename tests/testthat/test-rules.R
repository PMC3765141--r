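test_that("default registry ships all 17 indicator rule tables", {
  reg <- load_rule_registry()
  expect_s3_class(reg, "pr_rule_registry")
  expect_length(reg$tables, 17)
  expect_setequal(names(reg$tables),
                  c("1.1.1", "1.1.2", "1.1.3", "1.2.1", "1.2.2", "1.2.3",
                    "1.2.4", "2.1.1", "2.2.2", "3.1.1", "3.2.1", "3.2.2",
                    "3.3.1", "3.3.2", "3.3.3", "3.3.4", "3.3.5"))
  # the two erosion indicators share one threshold set
  expect_equal(reg$tables[["1.2.2"]]$rules[, c("min", "max", "class")],
               reg$tables[["3.3.4"]]$rules[, c("min", "max", "class")])
})

test_that("continuous thresholds classify published example values", {
  reg <- default_rule_registry()
  expect_equal(classify_value(reg$tables[["3.1.1"]], 1600), "MEDIUM")
  expect_equal(classify_value(reg$tables[["3.2.1"]], 5), "LOW")
  expect_equal(classify_value(reg$tables[["1.2.4"]], 85), "VERY_HIGH")
  expect_equal(classify_value(reg$tables[["1.2.2"]], 200), "VERY_HIGH")
  expect_equal(classify_value(reg$tables[["3.3.2"]], "sand"), "VERY_HIGH")
  expect_equal(classify_value(reg$tables[["3.1.1"]], NaN), "NODATA")
  expect_equal(classify_value(reg$tables[["3.3.1"]], NA), "NODATA")
})

test_that("boundary values take the less risky class", {
  reg <- default_rule_registry()
  expect_equal(classify_value(reg$tables[["3.2.1"]], c(8, 15, 30)),
               c("LOW", "MEDIUM", "HIGH"))
  expect_equal(classify_value(reg$tables[["3.1.1"]], c(1250, 1500, 1750, 5000)),
               c("HIGH", "MEDIUM", "LOW", "LOW"))
  expect_equal(classify_value(reg$tables[["1.2.4"]], c(60, 70, 80)),
               c("LOW", "MEDIUM", "HIGH"))
  expect_equal(classify_value(reg$tables[["3.3.3"]], c(50, 75, 100)),
               c("HIGH", "MEDIUM", "LOW"))
})

test_that("rainfall low band is two-sided and very-high is an interval union", {
  tab <- default_rule_registry()$tables[["3.1.1"]]
  expect_equal(classify_value(tab, c(600, 1100, 3000, 5500, 9000)),
               c("VERY_HIGH", "VERY_HIGH", "LOW", "VERY_HIGH", "VERY_HIGH"))
  vh <- tab$rules[tab$rules$class == "VERY_HIGH", ]
  expect_equal(nrow(vh), 2)
})

test_that("unknown categories fall to the default class with a warning", {
  reg <- default_rule_registry()
  expect_warning(out <- classify_value(reg$tables[["1.1.1"]], "farmland"),
                 "unknown categories")
  expect_equal(out, "LOW")           # "no overlap" default
  expect_warning(out2 <- classify_value(reg$tables[["3.3.2"]], "gravel"),
                 "unknown categories")
  expect_equal(out2, "NODATA")       # unrecognized soil class is not LOW
  expect_equal(suppressWarnings(
    classify_value(reg$tables[["3.3.1"]], c("Well", " IMPERFECT "))),
    c("LOW", "MEDIUM"))              # matching is case-insensitive, trimmed
})

test_that("malformed configs are rejected with the offending table named", {
  expect_error(rule_table("3.1.1", "continuous", rules = data.frame(
    min = 1750, max = 1500, class = "LOW")), "3\\.1\\.1.*malformed interval")
  expect_error(rule_table("x", "continuous", rules = data.frame(
    min = 0, max = 1, class = "EXTREME")), "unknown risk label")
  expect_error(rule_registry(list(
    rule_table("1.1.1", "categorical",
               rules = list(list(categories = "a", class = "LOW")),
               default_class = "LOW"),
    rule_table("1.1.1", "categorical",
               rules = list(list(categories = "b", class = "LOW")),
               default_class = "LOW"))), "duplicate indicator_id")
})

test_that("validator reports gaps and overlaps and accepts the defaults", {
  reg <- default_rule_registry()
  for (id in names(reg$tables)) {
    expect_equal(nrow(validate_rule_table(reg$tables[[id]])), 0,
                 label = paste("default table", id))
  }
  gap_tab <- rule_table("carbon-gap", "continuous", rules = data.frame(
    min = c(0, 70, 80), max = c(60, 80, Inf),
    min_closed = c(TRUE, FALSE, FALSE), max_closed = c(TRUE, TRUE, FALSE),
    class = c("LOW", "HIGH", "VERY_HIGH")))
  rep <- validate_rule_table(gap_tab)
  expect_true(any(rep$issue == "gap"))
  g <- rep[rep$issue == "gap", ][1, ]
  expect_equal(c(g$from, g$to), c(60, 70))
  ovl_tab <- rule_table("ovl", "continuous", rules = data.frame(
    min = c(0, 50), max = c(150, Inf),
    class = c("LOW", "HIGH")))
  rep2 <- validate_rule_table(ovl_tab)
  expect_true(any(rep2$issue == "overlap"))
  o <- rep2[rep2$issue == "overlap", ][1, ]
  expect_true(o$from <= 100 && o$to >= 100)   # both intervals contain 100
})

test_that("registry YAML round-trip is the identity", {
  reg <- default_rule_registry()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_rule_registry(path, reg)
  expect_equal(load_rule_registry(path), reg)
})

test_that("bare [min, max, class] triples load with the default convention", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "tables:",
    "  '9.9.9':",
    "    kind: continuous",
    "    units: t/ha",
    "    domain: [0, inf]",
    "    rules:",
    "      - [0, 60, LOW]",
    "      - [60, 70, MEDIUM]",
    "      - [70, inf, VERY_HIGH]"), path)
  reg <- load_rule_registry(path)
  expect_equal(nrow(validate_rule_table(reg$tables[["9.9.9"]])), 0)
  expect_equal(classify_value(reg$tables[["9.9.9"]], c(60, 61)),
               c("LOW", "MEDIUM"))
})

test_that("every default continuous table is a partition on a dense sweep", {
  reg <- default_rule_registry()
  for (id in names(reg$tables)) {
    tab <- reg$tables[[id]]
    if (tab$kind != "continuous") next
    hi <- max(tab$rules$max[is.finite(tab$rules$max)], tab$rules$min) * 1.5
    hi <- min(hi, tab$domain[2])
    sweep <- unique(c(seq(tab$domain[1], hi, length.out = 2001),
                      tab$rules$min[is.finite(tab$rules$min)],
                      tab$rules$max[is.finite(tab$rules$max)]))
    sweep <- sweep[sweep >= tab$domain[1] & sweep <= tab$domain[2]]
    hits <- palmrisk:::interval_contains(tab$rules, sweep)
    expect_true(all(rowSums(hits) == 1),
                label = paste("partition sweep for", id))
  }
})

test_that("monotone-hazard tables classify non-decreasingly in the value", {
  reg <- default_rule_registry()
  for (id in c("3.2.1", "3.2.2", "1.2.2", "3.3.4", "1.2.4", "2.1.1")) {
    tab <- reg$tables[[id]]
    hi <- min(max(tab$rules$max[is.finite(tab$rules$max)]) * 1.5,
              tab$domain[2])
    sweep <- seq(tab$domain[1], hi, length.out = 1500)
    rk <- risk_rank(classify_value(tab, sweep))
    expect_true(all(diff(rk) >= 0), label = paste("monotone hazard for", id))
  }
  # soil depth: hazard decreases with depth
  rk <- risk_rank(classify_value(reg$tables[["3.3.3"]],
                                 seq(0, 200, length.out = 1000)))
  expect_true(all(diff(rk) <= 0))
})

test_that("classify_grid equals the per-cell loop and preserves georeferencing", {
  reg <- default_rule_registry()
  tab <- reg$tables[["3.1.1"]]
  g <- pr_grid(matrix(c(1600, 1800, 1100, NA), 2, 2, byrow = TRUE),
               origin = c(300, 900), cell_size = 50, crs = "utm49s")
  lyr <- classify_grid(tab, g)
  expect_equal(lyr$cells, matrix(c(1L, 0L, 3L, NA), 2, 2, byrow = TRUE))
  expect_equal(lyr$origin, g$origin)
  expect_equal(lyr$cell_size, g$cell_size)
  expect_equal(lyr$crs, g$crs)
  # uniform grid -> uniform classes
  u <- classify_grid(tab, pr_grid(matrix(3000, 4, 5)))
  expect_true(all(u$cells == 0L))
  # oracle equivalence on a random grid
  set.seed(101)
  rg <- pr_grid(matrix(stats::runif(100 * 100, 0, 6000), 100, 100))
  expect_equal(classify_grid(tab, rg)$cells, bf_classify_grid(tab, rg))
})

test_that("shipped default rules file reproduces the built-in registry", {
  path <- system.file("extdata", "default_rules.yaml", package = "palmrisk")
  expect_equal(load_rule_registry(path), default_rule_registry())
})
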