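#' Spatially autocorrelated random field
#'
#' Generates a zero-mean, unit-variance Gaussian-like field by smoothing
#' white noise with an edge-normalized moving-average (box) kernel whose
#' radius is the requested correlation length in cells, then standardizing.
#' Correlation length 0 reduces to plain white noise. Deterministic under a
#' fixed seed.
#'
#' @param rows,cols positive grid dimensions.
#' @param correlation_length_cells kernel radius in cells (>= 0).
#' @param seed integer seed; \code{NULL} uses the current RNG state.
#' @return A numeric \code{rows x cols} matrix.
#' @examples
#' f <- correlated_field(50, 50, 3, seed = 1)
#' round(c(mean(f), stats::sd(f)), 6)
#' @export
correlated_field <- function(rows, cols, correlation_length_cells = 0,
                             seed = NULL) {
  if (rows < 1 || cols < 1) stop("grid dimensions must be positive")
  if (correlation_length_cells < 0) {
    stop("correlation_length_cells must be >= 0")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  m <- matrix(stats::rnorm(rows * cols), rows, cols)
  r <- as.integer(round(correlation_length_cells))
  if (r > 0) m <- box_smooth(m, r)
  (m - mean(m)) / stats::sd(m)
}

# edge-normalized box filter of radius r via a summed-area table
box_smooth <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  # summed-area table with a zero border
  P <- matrix(0, nr + 1, nc + 1)
  P[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  i1 <- pmax(1, seq_len(nr) - r); i2 <- pmin(nr, seq_len(nr) + r)
  j1 <- pmax(1, seq_len(nc) - r); j2 <- pmin(nc, seq_len(nc) + r)
  # window sums via the inclusion-exclusion identity, vectorized over rows
  S <- P[i2 + 1, j2 + 1] - P[i1, j2 + 1] - P[i2 + 1, j1] + P[i1, j1]
  counts <- outer(i2 - i1 + 1, j2 - j1 + 1)
  S / counts
}

#' Threshold a field into risk classes with target proportions
#'
#' Cuts a continuous field at its empirical quantiles so the realized class
#' proportions match the targets to within one cell (ties broken by cell
#' order), preserving the field's spatial structure. NODATA cells stay
#' NODATA and are excluded from the proportion accounting.
#'
#' @param field a \code{pr_grid} of reals (or a bare matrix).
#' @param proportions length-4 non-negative vector summing to 1
#'   (LOW/MEDIUM/HIGH/VERY_HIGH).
#' @param indicator_id id for the resulting layer.
#' @param ... passed to \code{pr_grid()} when \code{field} is a matrix.
#' @return A \code{pr_indicator_layer}.
#' @export
field_to_classes <- function(field, proportions, indicator_id = "synthetic",
                             ...) {
  if (is.matrix(field)) field <- pr_grid(field, ...)
  stopifnot(inherits(field, "pr_grid"))
  p <- check_proportions(proportions, 4)
  v <- as.vector(field$cells)
  ok <- which(!is.na(v))
  n <- length(ok)
  if (n == 0) stop("field has no valid cells")
  if (stats::sd(v[ok]) == 0 && sum(p > 0) > 1) {
    stop("degenerate (constant) field cannot be split into multiple classes")
  }
  cuts <- round(cumsum(p) * n); cuts[4] <- n
  rk <- rank(v[ok], ties.method = "first")
  cls <- findInterval(rk, c(0, cuts), left.open = TRUE, rightmost.closed = TRUE)
  out <- rep(NA_integer_, length(v))
  out[ok] <- as.integer(cls - 1L)
  indicator_layer(pr_grid(matrix(out, nrow(field$cells), ncol(field$cells)),
                          origin = field$origin, cell_size = field$cell_size,
                          crs = field$crs),
                  indicator_id = indicator_id)
}

check_proportions <- function(p, k) {
  p <- as.numeric(p)
  if (length(p) != k || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("proportions must be ", k, " non-negative values summing to 1")
  }
  p
}

#' Monotone value field matching class-band proportions
#'
#' Maps a continuous field through the inverse CDF of a piecewise-uniform
#' distribution over a continuous rule table's value bands, so that (a) the
#' transform is monotone in the field (spatial structure preserved) and (b)
#' classifying the result with that rule table recovers the requested class
#' proportions to within one cell. Where a class is an interval union (the
#' two-sided rainfall bands) its mass is split equally across its intervals;
#' an infinite upper bound is capped at 1.5 times the largest finite
#' breakpoint.
#'
#' @param field \code{pr_grid} of reals (or matrix).
#' @param table a continuous \code{pr_rule_table}.
#' @param proportions length-4 class proportions (LOW/MEDIUM/HIGH/VERY_HIGH).
#' @param ... passed to \code{pr_grid()} for bare matrices.
#' @return A \code{pr_grid} of indicator values in the table's units.
#' @export
band_value_field <- function(field, table, proportions, ...) {
  if (is.matrix(field)) field <- pr_grid(field, ...)
  stopifnot(inherits(field, "pr_grid"))
  stopifnot(inherits(table, "pr_rule_table"), table$kind == "continuous")
  p <- check_proportions(proportions, 4)
  rules <- table$rules[order(table$rules$min), ]
  per_class_n <- table(factor(rules$rank, levels = 0:3))
  absent <- which(per_class_n == 0) - 1L
  if (any(p[absent + 1L] > 0)) {
    stop("rule table ", table$indicator_id, " has no band for class ",
         paste(risk_label(absent[p[absent + 1L] > 0]), collapse = ", "),
         " but a positive proportion was requested")
  }
  mass <- p[rules$rank + 1] / as.numeric(per_class_n[as.character(rules$rank)])
  fin_max <- max(rules$max[is.finite(rules$max)], rules$min)
  lo <- rules$min
  hi <- ifelse(is.finite(rules$max), rules$max, fin_max * 1.5)
  eps <- (hi - lo) * 1e-9
  # keep sampled values strictly inside open endpoints
  lo_in <- ifelse(rules$min_closed, lo, lo + eps)
  hi_in <- ifelse(rules$max_closed & is.finite(rules$max), hi, hi - eps)
  v <- as.vector(field$cells)
  ok <- which(!is.na(v))
  n <- length(ok)
  cuts <- round(cumsum(mass) * n); cuts[length(cuts)] <- n
  starts <- c(0, utils::head(cuts, -1))
  rk <- rank(v[ok], ties.method = "first")
  band <- findInterval(rk, c(0, cuts), left.open = TRUE,
                       rightmost.closed = TRUE)
  within <- (rk - starts[band] - 0.5) / pmax(cuts[band] - starts[band], 1)
  vals <- lo_in[band] + within * (hi_in[band] - lo_in[band])
  out <- rep(NA_real_, length(v))
  out[ok] <- vals
  pr_grid(matrix(out, nrow(field$cells), ncol(field$cells)),
          origin = field$origin, cell_size = field$cell_size,
          crs = field$crs)
}

#' Random simple polygons
#'
#' Draws star-shaped (hence simple, non-self-intersecting) polygons with
#' jittered vertex radii, rescaled so each polygon's exact (shoelace) area
#' equals a target drawn uniformly from \code{size_range_ha}. Centers are
#' placed so the polygon stays inside \code{extent}. Deterministic under a
#' fixed seed.
#'
#' @param n number of polygons (>= 0).
#' @param size_range_ha length-2 polygon area range in hectares.
#' @param extent numeric length-4: xmin, xmax, ymin, ymax (map metres).
#' @param seed integer seed; \code{NULL} uses the current RNG state.
#' @param crs CRS identifier for the resulting set.
#' @return A \code{pr_polygons}.
#' @export
random_polygons <- function(n, size_range_ha = c(50, 500),
                            extent = c(0, 10000, 0, 10000), seed = NULL,
                            crs = "local-projected") {
  stopifnot(n >= 0, length(size_range_ha) == 2, all(size_range_ha > 0))
  if (!is.null(seed)) set.seed(as.integer(seed))
  feats <- vector("list", n)
  if (n == 0) return(pr_polygons(list(), crs = crs))
  for (i in seq_len(n)) {
    target_m2 <- stats::runif(1, size_range_ha[1], size_range_ha[2]) * 1e4
    k <- sample(8:12, 1)
    ang <- sort(stats::runif(k, 0, 2 * pi))
    rad <- stats::runif(k, 0.7, 1.3)
    x <- rad * cos(ang); y <- rad * sin(ang)
    # shoelace area of the unit-scale star, then exact rescale
    a0 <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
    s <- sqrt(target_m2 / a0)
    x <- x * s; y <- y * s
    rmax <- max(sqrt(x^2 + y^2))
    cx <- stats::runif(1, extent[1] + rmax, max(extent[2] - rmax,
                                                extent[1] + rmax))
    cy <- stats::runif(1, extent[3] + rmax, max(extent[4] - rmax,
                                                extent[3] + rmax))
    feats[[i]] <- list(rings = list(cbind(cx + x, cy + y)),
                       properties = list(id = i,
                                         target_ha = target_m2 / 1e4))
  }
  pr_polygons(feats, crs = crs)
}

#' Synthetic scenario specification
#'
#' Describes a province-like synthetic input bundle: grid geometry, a seed,
#' per-indicator layer specs, and polygon/zone specs. Layer specs come in
#' two forms: \code{list(proportions = <4-vector>, correlation_length_m =
#' <m>)} for class layers, optionally with \code{values = TRUE} to also emit
#' a raw value grid for continuous indicators (classifiable back to the same
#' classes via the rule registry); the default layer set reproduces the
#' published seven-layer marginal distribution.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param cell_size_m cell edge, metres (default 100 m = 1 ha cells).
#' @param seed integer master seed; all randomness in
#'   \code{\link{generate_scenario}} funnels through it.
#' @param layers named list (by indicator id) of layer specs; defaults to the
#'   published seven-layer marginals with a 500 m correlation length.
#' @param lup_proportions length-4 proportions of the land-use-plan zones
#'   (other use, conversion forest, production forest, protection forest).
#' @param concessions list with counts and size ranges for active/inactive
#'   concession polygons.
#' @param protected list with count and size range for protected-area
#'   polygons.
#' @param correlation_length_m default spatial correlation length, metres.
#' @param crs CRS identifier stamped on every generated object.
#' @return An object of class \code{pr_scenario_spec}.
#' @export
scenario_spec <- function(n_rows = 100, n_cols = 100, cell_size_m = 100,
                          seed = 1, layers = NULL,
                          lup_proportions = c(0.25, 0.10, 0.35, 0.30),
                          concessions = list(n_active = 3, n_inactive = 4,
                                             size_range_ha = c(200, 1200)),
                          protected = list(n = 2,
                                           size_range_ha = c(300, 1500)),
                          correlation_length_m = 500,
                          crs = "local-projected") {
  if (n_rows < 1 || n_cols < 1) stop("scenario dimensions must be positive")
  if (is.null(layers)) {
    props <- reference_layer_proportions()
    continuous_ids <- c("1.2.2", "1.2.4", "3.1.1")
    layers <- lapply(names(props), function(id) {
      list(proportions = props[[id]],
           correlation_length_m = correlation_length_m,
           values = id %in% continuous_ids)
    })
    names(layers) <- names(props)
  }
  for (id in names(layers)) {
    layers[[id]]$proportions <- check_proportions(layers[[id]]$proportions, 4)
    if (is.null(layers[[id]]$correlation_length_m)) {
      layers[[id]]$correlation_length_m <- correlation_length_m
    }
    if (is.null(layers[[id]]$values)) layers[[id]]$values <- FALSE
  }
  check_proportions(lup_proportions, 4)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size_m = cell_size_m, seed = as.integer(seed),
                 layers = layers, lup_proportions = lup_proportions,
                 concessions = concessions, protected = protected,
                 correlation_length_m = correlation_length_m, crs = crs),
            class = "pr_scenario_spec")
}

#' Generate a synthetic input bundle
#'
#' Produces a grid-congruent bundle ready for the full pipeline: one class
#' layer per configured indicator (realized class proportions within one
#' cell of the targets), raw value grids for continuous indicators flagged
#' with \code{values = TRUE}, protected-area and concession polygons with a
#' rasterized protected mask, concession-status and land-use-plan zone maps,
#' and a manifest recording the spec and seed. Identical spec and seed give
#' identical bundles.
#'
#' @param spec a \code{pr_scenario_spec}.
#' @return A list of class \code{pr_scenario_bundle} with elements
#'   \code{layers}, \code{values}, \code{protected_polygons},
#'   \code{protected_mask}, \code{concession_polygons}, \code{zones}
#'   (list: \code{concessions}, \code{land_use_plan}) and \code{manifest}.
#' @examples
#' b <- generate_scenario(scenario_spec(n_rows = 20, n_cols = 20, seed = 7))
#' names(b$layers)
#' @export
generate_scenario <- function(spec) {
  stopifnot(inherits(spec, "pr_scenario_spec"))
  set.seed(spec$seed)
  nr <- spec$n_rows; nc <- spec$n_cols; cs <- spec$cell_size_m
  template <- pr_grid(matrix(0, nr, nc), origin = c(0, nr * cs),
                      cell_size = cs, crs = spec$crs)
  as_grid <- function(m) pr_grid(m, origin = template$origin,
                                 cell_size = cs, crs = spec$crs)
  reg <- default_rule_registry()
  layers <- list(); values <- list()
  for (id in names(spec$layers)) {
    ls <- spec$layers[[id]]
    L <- ls$correlation_length_m / cs
    f <- as_grid(correlated_field(nr, nc, L))
    if (isTRUE(ls$values)) {
      tab <- reg$tables[[id]]
      if (is.null(tab) || tab$kind != "continuous") {
        stop("scenario layer ", id,
             ": values=TRUE needs a continuous rule table")
      }
      values[[id]] <- band_value_field(f, tab, ls$proportions)
      # class layer derived from the value grid so the bundle is
      # self-consistent: classify(values) == layers[[id]]
      layers[[id]] <- classify_grid(tab, values[[id]])
    } else {
      layers[[id]] <- field_to_classes(f, ls$proportions, indicator_id = id)
    }
  }
  extent <- c(0, nc * cs, 0, nr * cs)
  protected <- random_polygons(spec$protected$n,
                               spec$protected$size_range_ha, extent,
                               crs = spec$crs)
  protected_mask <- rasterize_polygons(protected, template)
  n_act <- spec$concessions$n_active; n_inact <- spec$concessions$n_inactive
  conc <- random_polygons(n_act + n_inact, spec$concessions$size_range_ha,
                          extent, crs = spec$crs)
  for (i in seq_along(conc$features)) {
    conc$features[[i]]$properties$status <-
      if (i <= n_act) "active" else "inactive"
  }
  conc_cells <- matrix(0L, nr, nc)
  for (i in rev(seq_along(conc$features))) {   # active polygons win overlaps
    one <- pr_polygons(list(conc$features[[i]]), crs = spec$crs)
    m <- rasterize_polygons(one, template)
    code <- if (conc$features[[i]]$properties$status == "active") 1L else 2L
    conc_cells[m$cells == 1L] <- code
  }
  zones_conc <- zone_map(as_grid(conc_cells),
                         c("0" = "none", "1" = "active", "2" = "inactive"))
  lup_field <- as_grid(correlated_field(nr, nc,
                                        spec$correlation_length_m / cs))
  lup_cls <- field_to_classes(lup_field, spec$lup_proportions, "lup")
  zones_lup <- zone_map(as_grid(lup_cls$cells + 1L),
                        c("1" = "other use", "2" = "conversion forest",
                          "3" = "production forest",
                          "4" = "protection forest"))
  manifest <- list(spec = unclass(spec), seed = spec$seed,
                   n_rows = nr, n_cols = nc, cell_size_m = cs,
                   crs = spec$crs, layer_ids = names(spec$layers))
  structure(list(layers = layers, values = values,
                 protected_polygons = protected,
                 protected_mask = protected_mask,
                 concession_polygons = conc,
                 zones = list(concessions = zones_conc,
                              land_use_plan = zones_lup),
                 template = template, manifest = manifest),
            class = "pr_scenario_bundle")
}

#' @export
print.pr_scenario_bundle <- function(x, ...) {
  cat(sprintf("<pr_scenario_bundle> %d x %d cells, %d layer(s): %s\n",
              x$manifest$n_rows, x$manifest$n_cols, length(x$layers),
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}
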