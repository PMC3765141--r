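test_that("maximum-risk overlay: worst class overrules, identity on one layer", {
  a <- indicator_layer(matrix(c(0L, 2L, 3L, 0L), 2, 2), "a")
  b <- indicator_layer(matrix(c(2L, 1L, 0L, 0L), 2, 2), "b")
  c3 <- indicator_layer(matrix(c(3L, 0L, 1L, 0L), 2, 2), "c")
  rim <- combine_liebig(list(a, b, c3))
  expect_equal(rim$cells, matrix(c(3L, 2L, 3L, 0L), 2, 2))
  expect_equal(combine_liebig(list(a))$cells, a$cells)
  expect_error(combine_liebig(list()), "non-empty")
  bad <- indicator_layer(matrix(0L, 3, 2), "bad")
  expect_error(combine_liebig(list(a, bad)), "congruent")
})

test_that("overlay nodata policies: ignore keeps partial coverage, propagate does not", {
  a <- indicator_layer(matrix(c(0L, NA, NA, 1L), 2, 2), "a")
  b <- indicator_layer(matrix(c(2L, 3L, NA, NA), 2, 2), "b")
  ign <- combine_liebig(list(a, b), "ignore")
  expect_equal(ign$cells, matrix(c(2L, 3L, NA, 1L), 2, 2))
  prop <- combine_liebig(list(a, b), "propagate")
  expect_equal(prop$cells, matrix(c(2L, NA, NA, NA), 2, 2))
})

test_that("overlay is permutation- and duplication-invariant and matches the oracle", {
  set.seed(99)
  layers <- lapply(1:7, function(i) random_layer(20, 20, p_na = 0.05))
  rim <- combine_liebig(layers)
  expect_equal(rim$cells, bf_combine(layers, "ignore"))
  perm <- combine_liebig(layers[sample(7)])
  expect_equal(perm$cells, rim$cells)
  dup <- combine_liebig(c(layers, layers[3]))
  expect_equal(dup$cells, rim$cells)
  # Liebig dominance: combined rank >= each layer's rank
  for (l in layers) {
    both <- !is.na(rim$cells) & !is.na(l$cells)
    expect_true(all(rim$cells[both] >= l$cells[both]))
  }
})

test_that("adding layers never increases combined LOW area; LOW region is the intersection", {
  set.seed(17)
  layers <- lapply(1:5, function(i) random_layer(25, 25))
  low_area <- function(rim) sum(rim$cells == 0L, na.rm = TRUE)
  prev <- Inf
  for (k in 1:5) {
    a <- low_area(combine_liebig(layers[1:k]))
    expect_lte(a, prev)
    prev <- a
  }
  rim <- combine_liebig(layers)
  inter <- Reduce(`&`, lapply(layers, function(l) l$cells == 0L))
  expect_equal(rim$cells == 0L, inter)
})

test_that("area tables: counts, hectares and half-up integer percentages", {
  all_low <- indicator_layer(matrix(0L, 10, 10), "x", cell_size = 100)
  at <- tabulate_areas(all_low)
  expect_equal(at$low_ha, 100)
  expect_equal(at$low_pct, 100L)
  expect_equal(at$medium_ha + at$high_ha + at$very_high_ha, 0)
  cells <- c(rep(0L, 20), rep(2L, 10), rep(3L, 70))
  lyr <- indicator_layer(matrix(cells, 10, 10), "y", cell_size = 100)
  at2 <- tabulate_areas(lyr)
  expect_equal(c(at2$low_pct, at2$high_pct, at2$very_high_pct),
               c(20L, 10L, 70L))
  expect_equal(at2$total_ha, 100)
  # NODATA excluded from the total
  cells[1:10] <- NA
  at3 <- tabulate_areas(indicator_layer(matrix(cells, 10, 10), "z",
                                        cell_size = 100))
  expect_equal(at3$total_ha, 90)
  # half-up rounding, not banker's
  expect_equal(round_half_up(c(0.5, 1.5, 2.5, -0.2)), c(1L, 2L, 3L, 0L))
  set.seed(3)
  rl <- random_layer(30, 30, p_na = 0.1)
  at4 <- tabulate_areas(rl)
  expect_equal(as.numeric(at4[1, c("low_ha", "medium_ha", "high_ha",
                                   "very_high_ha")]),
               bf_class_counts(rl) * cell_area_ha(rl))
})

test_that("cross-tabulation partitions the map and reduces to tabulate for one zone", {
  set.seed(41)
  rim <- random_layer(20, 20)
  one <- zone_map(matrix(1L, 20, 20), c("1" = "all"),
                  cell_size = 100)
  ct <- cross_tabulate(rim, one)
  ta <- tabulate_areas(rim, label = "all")
  expect_equal(as.data.frame(ct), as.data.frame(ta))
  halves <- zone_map(matrix(rep(c(1L, 2L), each = 200), 20, 20),
                     c("1" = "west", "2" = "east"), cell_size = 100)
  ct2 <- cross_tabulate(rim, halves)
  expect_equal(sum(ct2$total_ha), mapped_area_ha(rim))
  # joint-histogram oracle on random zones
  zc <- matrix(sample(1:4, 400, replace = TRUE), 20, 20)
  zm <- zone_map(zc, c("1" = "a", "2" = "b", "3" = "c", "4" = "d"),
                 cell_size = 100)
  ct3 <- cross_tabulate(rim, zm)
  want <- bf_cross_counts(rim, zm) * cell_area_ha(rim)
  got <- as.matrix(as.data.frame(ct3)[, c("low_ha", "medium_ha", "high_ha",
                                          "very_high_ha")])
  expect_equal(unname(got), unname(want))
  expect_error(cross_tabulate(rim, zone_map(matrix(1L, 5, 5), c("1" = "x"))),
               "congruent")
})

test_that("map-denominator percentages express zone shares of the whole map", {
  rim <- indicator_layer(matrix(c(rep(0L, 50), rep(3L, 50)), 10, 10), "rim",
                         cell_size = 100)
  zm <- zone_map(matrix(rep(c(1L, 2L), each = 50), 10, 10),
                 c("1" = "a", "2" = "b"), cell_size = 100)
  ct <- cross_tabulate(rim, zm, percent_denominator = "map")
  expect_equal(ct$low_pct, c(50L, 0L))   # 50 of 100 mapped ha
  ct_zone <- cross_tabulate(rim, zm, percent_denominator = "zone")
  expect_equal(ct_zone$low_pct, c(100L, 0L))
})

test_that("expansion ranking reports low-risk land by legal-class priority", {
  dict_lup <- c("1" = "other use", "2" = "conversion forest",
                "3" = "production forest", "4" = "protection forest")
  dict_con <- c("0" = "none", "1" = "active", "2" = "inactive")
  n <- 10
  all_vh <- indicator_layer(matrix(3L, n, n), "rim", cell_size = 100)
  lup <- zone_map(matrix(1L, n, n), dict_lup, cell_size = 100)
  con <- zone_map(matrix(0L, n, n), dict_con, cell_size = 100)
  rec <- rank_expansion_options(all_vh, lup, con)
  expect_true(all(rec$low_risk_ha == 0))
  expect_equal(rec$priority, 0:4)
  expect_equal(rec$zone[2:5], c("other use", "conversion forest",
                                "production forest", "protection forest"))
  all_low <- indicator_layer(matrix(0L, n, n), "rim", cell_size = 100)
  rec2 <- rank_expansion_options(all_low, lup, con)
  expect_equal(rec2$low_risk_ha[rec2$zone == "other use"], 100)
  # oracle via cross_tabulate on random inputs
  set.seed(88)
  rim <- random_layer(n, n)
  lupr <- zone_map(matrix(sample(1:4, n * n, TRUE), n, n), dict_lup,
                   cell_size = 100)
  conr <- zone_map(matrix(sample(0:2, n * n, TRUE, prob = c(.6, .2, .2)),
                          n, n), dict_con, cell_size = 100)
  rec3 <- rank_expansion_options(rim, lupr, conr)
  inact <- cross_tabulate(rim, conr)
  expect_equal(rec3$low_risk_ha[1], inact$low_ha[inact$label == "inactive"])
  for (k in 1:4) {
    sel <- rim$cells == 0L & conr$cells != 1L & lupr$cells == k
    expect_equal(rec3$low_risk_ha[k + 1],
                 sum(sel, na.rm = TRUE) * cell_area_ha(rim))
  }
  bad <- zone_map(matrix(1L, n, n), c("1" = "wetland"), cell_size = 100)
  expect_error(rank_expansion_options(rim, bad, conr), "unknown zone label")
})
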