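#' Rule registry: the full suitability classification
#'
#' A registry holds one rule table per indicator, keyed by the dotted
#' indicator code of the principle/criterion/indicator hierarchy. The
#' built-in default encodes the complete published suitability
#' classification: 17 indicators under three principles (biodiversity and
#' ecosystem services; community wellbeing and land rights; biophysical
#' suitability).
#'
#' Two indicators (1.2.2 general erosion risk and 3.3.4 soil erosion risk)
#' share one set of erosion thresholds, encoded once and referenced twice.
#' Two tables are three-class partitions (1.1.1 has no HIGH band, 1.2.3 no
#' MEDIUM band: no data supported a fourth band); the validator accepts
#' these.
#'
#' @param tables named list of \code{pr_rule_table}s keyed by indicator id.
#' @param metadata named list of per-indicator principle/criterion text.
#' @return An object of class \code{pr_rule_registry}.
#' @seealso \code{\link{load_rule_registry}}, \code{\link{classify_grid}}
#' @export
rule_registry <- function(tables, metadata = list()) {
  ids <- vapply(tables, function(t) t$indicator_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate indicator_id in registry: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(tables) <- ids
  structure(list(tables = tables, metadata = metadata),
            class = "pr_rule_registry")
}

#' @export
print.pr_rule_registry <- function(x, ...) {
  cat(sprintf("<pr_rule_registry> %d rule tables: %s\n",
              length(x$tables), paste(names(x$tables), collapse = ", ")))
  invisible(x)
}

# Half-open bands for a hazard that increases with the value: the boundary
# value takes the less risky (lower) class, so bands are (a, b] with the
# first band closed at the domain minimum.
increasing_bands <- function(breaks, classes, domain = c(0, Inf)) {
  k <- length(classes)
  stopifnot(length(breaks) == k - 1)
  lo <- c(domain[1], breaks)
  hi <- c(breaks, domain[2])
  data.frame(min = lo, max = hi,
             min_closed = c(TRUE, rep(FALSE, k - 1)),
             max_closed = c(rep(TRUE, k - 1), is.finite(domain[2])),
             class = classes, stringsAsFactors = FALSE)
}

# Bands for a hazard that decreases with the value: boundary goes to the
# less risky (upper) class, so bands are [a, b) with the last band closed
# at a finite domain maximum.
decreasing_bands <- function(breaks, classes, domain = c(0, Inf)) {
  k <- length(classes)
  stopifnot(length(breaks) == k - 1)
  lo <- c(domain[1], breaks)
  hi <- c(breaks, domain[2])
  data.frame(min = lo, max = hi,
             min_closed = c(TRUE, rep(TRUE, k - 1)),
             max_closed = c(rep(FALSE, k - 1), is.finite(domain[2])),
             class = classes, stringsAsFactors = FALSE)
}

erosion_rules <- function() {
  # shared by 1.2.2 and 3.3.4: <15 low, 15-60 medium, 60-180 high, >180
  # very high (t/ha/yr)
  increasing_bands(c(15, 60, 180), c("LOW", "MEDIUM", "HIGH", "VERY_HIGH"))
}

#' @rdname rule_registry
#' @export
default_rule_registry <- function() {
  meta <- list(
    "1.1.1" = "P1 conservation values / C1.1 biodiversity: formal protection and conservation areas (HCV 1.1)",
    "1.1.2" = "P1 conservation values / C1.1 biodiversity: distribution and habitats of protected and endangered species (HCV 1.2-1.4)",
    "1.1.3" = "P1 conservation values / C1.1 biodiversity: endangered ecosystems and large intact forest (HCV 2 & 3)",
    "1.2.1" = "P1 conservation values / C1.2 ecosystem services: hydrological functions (HCV 4.1)",
    "1.2.2" = "P1 conservation values / C1.2 ecosystem services: erosion risk (HCV 4.2)",
    "1.2.3" = "P1 conservation values / C1.2 ecosystem services: buffer zones against large-scale fire (HCV 4.3)",
    "1.2.4" = "P1 conservation values / C1.2 ecosystem services: carbon stocks",
    "2.1.1" = "P2 human wellbeing / C2.1 community use: provisioning services for subsistence (HCV 5) or cultural sites (HCV 6)",
    "2.2.2" = "P2 human wellbeing / C2.1 community use: customary land rights",
    "3.1.1" = "P3 biophysical suitability / C3.1 climate: rainfall",
    "3.2.1" = "P3 biophysical suitability / C3.2 topography: slope",
    "3.2.2" = "P3 biophysical suitability / C3.2 topography: elevation",
    "3.3.1" = "P3 biophysical suitability / C3.3 soil: drainage",
    "3.3.2" = "P3 biophysical suitability / C3.3 soil: texture",
    "3.3.3" = "P3 biophysical suitability / C3.3 soil: depth",
    "3.3.4" = "P3 biophysical suitability / C3.3 soil: erosion risk",
    "3.3.5" = "P3 biophysical suitability / C3.3 soil: chemical properties"
  )
  cat_rule <- function(class, ...) list(categories = c(...), class = class)
  tables <- list(
    rule_table("1.1.1", "categorical", rules = list(
      cat_rule("MEDIUM", "bufferzones1km"),
      cat_rule("VERY_HIGH", "iucn i-iv", "iucn v-vii", "protected forest",
               "ramsar", "national conservation area")
    ), default_class = "LOW"),
    rule_table("1.1.2", "categorical", rules = list(
      cat_rule("MEDIUM", "species distribution"),
      cat_rule("HIGH", "species habitat"),
      cat_rule("VERY_HIGH", "breeding grounds", "nesting places",
               "grazing/browsing for endangered species",
               "temporal habitat migratory species")
    ), default_class = "LOW"),
    rule_table("1.1.3", "categorical", rules = list(
      cat_rule("MEDIUM", "forest area >20000 ha plus buffer 3 km"),
      cat_rule("HIGH", "2 or more eco-tone regions", "endangered ecosystem"),
      cat_rule("VERY_HIGH", "karst class 1", "peat", "fresh water swamp",
               "mangrove", "hutan kerangas", "cloud rainforest")
    ), default_class = "LOW"),
    rule_table("1.2.1", "categorical", rules = list(
      cat_rule("MEDIUM", "das super priority"),
      cat_rule("HIGH", "mangrove", "peat", "wetland", "karst forest",
               "cloud forest", "hutan punggung"),
      cat_rule("VERY_HIGH", "water source", "riparian zone",
               "water source buffer zone")
    ), default_class = "LOW"),
    rule_table("1.2.2", "continuous", units = "t/ha/yr",
               rules = erosion_rules()),
    rule_table("1.2.3", "categorical", rules = list(
      cat_rule("HIGH", "fire barrier, (partly) burned in last 10 years"),
      cat_rule("VERY_HIGH", "fire barrier, not burned in last 10 years")
    ), default_class = "LOW"),
    rule_table("1.2.4", "continuous", units = "t/ha",
               rules = increasing_bands(c(60, 70, 80),
                                        c("LOW", "MEDIUM", "HIGH",
                                          "VERY_HIGH"))),
    rule_table("2.1.1", "continuous", units = "% subsistence provision",
               domain = c(0, 100),
               rules = increasing_bands(c(10, 25, 50),
                                        c("LOW", "MEDIUM", "HIGH",
                                          "VERY_HIGH"),
                                        domain = c(0, 100))),
    rule_table("2.2.2", "categorical", rules = list(
      cat_rule("MEDIUM", "idle land, community interested to change use"),
      cat_rule("HIGH", "idle land, tanah pera",
               "idle land, community not interested to change use"),
      cat_rule("VERY_HIGH", "tembawang", "simpung", "limbo", "tana' jaka",
               "tana' ulen", "gupung", "community protected forest",
               "active use of land")
    ), default_class = "LOW"),
    # rainfall: the low band is two-sided (1750-5000 mm/yr), very high is
    # the union < 1250 and > 5000 — an explicit union of intervals
    rule_table("3.1.1", "continuous", units = "mm/yr", rules = data.frame(
      min = c(0, 1250, 1500, 1750, 5000),
      max = c(1250, 1500, 1750, 5000, Inf),
      min_closed = c(TRUE, TRUE, TRUE, TRUE, FALSE),
      max_closed = c(FALSE, FALSE, FALSE, TRUE, FALSE),
      class = c("VERY_HIGH", "HIGH", "MEDIUM", "LOW", "VERY_HIGH"),
      stringsAsFactors = FALSE
    )),
    rule_table("3.2.1", "continuous", units = "%",
               rules = increasing_bands(c(8, 15, 30),
                                        c("LOW", "MEDIUM", "HIGH",
                                          "VERY_HIGH"))),
    rule_table("3.2.2", "continuous", units = "m",
               rules = increasing_bands(c(200, 500, 1000),
                                        c("LOW", "MEDIUM", "HIGH",
                                          "VERY_HIGH"))),
    rule_table("3.3.1", "categorical", rules = list(
      cat_rule("LOW", "well", "moderately well"),
      cat_rule("MEDIUM", "imperfect"),
      cat_rule("HIGH", "extreme", "poor"),
      cat_rule("VERY_HIGH", "excessive", "very poor", "stagnant")
    ), default_class = "NODATA"),
    rule_table("3.3.2", "categorical", rules = list(
      cat_rule("LOW", "silt loam", "sandy clay loam", "silty clay loam",
               "clay loam"),
      cat_rule("MEDIUM", "clay", "silty clay", "sandy loam", "loam"),
      cat_rule("HIGH", "sandy clay", "silt", "loamy sand"),
      cat_rule("VERY_HIGH", "heavy clay", "sand")
    ), default_class = "NODATA"),
    # soil depth: hazard decreases with depth; >100 cm is low risk and the
    # boundary value takes the deeper (less risky) band
    rule_table("3.3.3", "continuous", units = "cm",
               rules = decreasing_bands(c(50, 75, 100),
                                        c("VERY_HIGH", "HIGH", "MEDIUM",
                                          "LOW"))),
    rule_table("3.3.4", "continuous", units = "t/ha/yr",
               rules = erosion_rules()),
    rule_table("3.3.5", "categorical", rules = list(
      cat_rule("LOW", "nitisols", "alfisols"),
      cat_rule("MEDIUM", "tropudults", "ultisol"),
      cat_rule("HIGH", "lithic dystrudepts", "inceptisol"),
      cat_rule("VERY_HIGH", "tropopsamment", "placaquods", "sulfihemist",
               "sulfaquept", "sulfaquent")
    ), default_class = "NODATA")
  )
  for (i in seq_along(tables)) {
    tables[[i]]$metadata <- list(description = meta[[tables[[i]]$indicator_id]])
  }
  rule_registry(tables, metadata = meta)
}

#' Load / write a rule registry as a structured config file
#'
#' The registry serializes to a YAML document with one block per indicator
#' (fields: \code{kind}, \code{units}, \code{domain}, \code{default},
#' \code{rules}). Continuous rules may be written either as mappings with
#' explicit \code{min}/\code{max}/\code{min_closed}/\code{max_closed}/
#' \code{class} fields or as bare \code{[min, max, class]} triples (the
#' built-in boundary convention then applies); categorical rules are
#' \code{\{categories: [...], class: ...\}}. Calling
#' \code{load_rule_registry()} with no path returns the built-in default
#' classification.
#'
#' @param path YAML file path; \code{NULL} loads the built-in defaults.
#' @return \code{load_rule_registry()} returns a \code{pr_rule_registry};
#'   \code{write_rule_registry()} returns \code{path} invisibly.
#' @examples
#' reg <- load_rule_registry()
#' length(reg$tables)
#' @export
load_rule_registry <- function(path = NULL) {
  if (is.null(path)) return(default_rule_registry())
  doc <- yaml::read_yaml(path)
  if (is.null(doc$tables)) stop("registry config has no 'tables' block: ", path)
  ids <- names(doc$tables)
  if (anyDuplicated(ids)) {
    stop("duplicate indicator_id in config: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  tables <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]; blk <- doc$tables[[i]]
    if (is.null(blk$kind)) stop("table ", id, ": missing 'kind'")
    if (blk$kind == "continuous") {
      dom <- if (is.null(blk$domain)) c(0, Inf) else {
        d <- blk$domain
        c(as.numeric(d[[1]]),
          if (is.character(d[[2]]) && d[[2]] %in% c("inf", ".inf", "Inf"))
            Inf else as.numeric(d[[2]]))
      }
      rules <- lapply(blk$rules, function(r) {
        if (is.null(names(r))) {       # bare [min, max, class] triple
          list(min = as.numeric(r[[1]]), max = as.numeric(r[[2]]),
               class = as.character(r[[3]]))
        } else r
      })
      rules <- lapply(rules, function(r) {
        for (f in c("min", "max")) {
          if (is.character(r[[f]])) {
            r[[f]] <- switch(r[[f]], "inf" = , ".inf" = , "Inf" = Inf,
                             "-inf" = , "-.inf" = , "-Inf" = -Inf,
                             as.numeric(r[[f]]))
          }
        }
        r
      })
      tables[[i]] <- rule_table(id, "continuous", units = blk$units,
                                rules = rules, domain = dom,
                                metadata = as.list(blk$metadata))
    } else if (blk$kind == "categorical") {
      tables[[i]] <- rule_table(id, "categorical", rules = blk$rules,
                                default_class = blk$default,
                                metadata = as.list(blk$metadata))
    } else {
      stop("table ", id, ": unknown kind '", blk$kind, "'")
    }
  }
  rule_registry(tables,
                metadata = stats::setNames(lapply(tables, function(t)
                  t$metadata$description), ids))
}

#' @rdname load_rule_registry
#' @param registry a \code{pr_rule_registry}.
#' @export
write_rule_registry <- function(path, registry) {
  stopifnot(inherits(registry, "pr_rule_registry"))
  blocks <- lapply(registry$tables, function(t) {
    if (t$kind == "continuous") {
      list(kind = "continuous", units = t$units,
           domain = list(t$domain[1],
                         if (is.finite(t$domain[2])) t$domain[2] else "inf"),
           metadata = t$metadata,
           rules = lapply(seq_len(nrow(t$rules)), function(i) {
             r <- t$rules[i, ]
             list(min = if (is.finite(r$min)) r$min else "-inf",
                  max = if (is.finite(r$max)) r$max else "inf",
                  min_closed = r$min_closed, max_closed = r$max_closed,
                  class = r$class)
           }))
    } else {
      list(kind = "categorical", default = t$default_class,
           metadata = t$metadata,
           rules = lapply(t$rules, function(r)
             list(categories = as.list(r$categories), class = r$class)))
    }
  })
  yaml::write_yaml(list(tables = blocks), path)
  invisible(path)
}
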