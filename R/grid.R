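#' Georeferenced raster grid
#'
#' A minimal single-band raster: a matrix of cell values plus the
#' georeferencing needed for area accounting and overlay congruence checks.
#' Cells are square; the coordinate system is assumed projected and
#' equal-area, so cell area in hectares is \code{cell_size^2 / 1e4}.
#' Row 1 is the northernmost row (map convention); \code{origin} is the
#' map coordinate of the upper-left corner of cell (1,1).
#'
#' @param cells matrix (numeric, integer or character) of cell values;
#'   \code{NA} is nodata.
#' @param origin numeric length-2, map x/y of the upper-left grid corner.
#' @param cell_size cell edge length in metres (square cells).
#' @param crs identifier of the (projected, equal-area assumed) CRS.
#' @return An object of class \code{pr_grid}.
#' @examples
#' g <- pr_grid(matrix(1:6, 2, 3), cell_size = 100)
#' cell_area_ha(g)
#' @export
pr_grid <- function(cells, origin = c(0, 0), cell_size = 100,
                    crs = "local-projected") {
  if (!is.matrix(cells)) stop("cells must be a matrix")
  if (nrow(cells) < 1 || ncol(cells) < 1) stop("grid dimensions must be positive")
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0) {
    stop("cell_size must be a single positive number of metres")
  }
  structure(
    list(cells = cells, origin = as.numeric(origin[1:2]),
         cell_size = as.numeric(cell_size), crs = as.character(crs)),
    class = "pr_grid"
  )
}

#' @rdname pr_grid
#' @param g a \code{pr_grid}.
#' @return \code{cell_area_ha()}: area of one cell in hectares.
#' @export
cell_area_ha <- function(g) {
  stopifnot(inherits(g, "pr_grid"))
  g$cell_size^2 / 1e4
}

#' @rdname pr_grid
#' @return \code{mapped_area_ha()}: total area of non-nodata cells, hectares.
#' @export
mapped_area_ha <- function(g) {
  sum(!is.na(g$cells)) * cell_area_ha(g)
}

#' @rdname pr_grid
#' @param a,b two \code{pr_grid}s.
#' @return \code{grid_congruent()}: TRUE iff origin, cell size, dimensions and
#'   CRS all match.
#' @export
grid_congruent <- function(a, b) {
  stopifnot(inherits(a, "pr_grid"), inherits(b, "pr_grid"))
  isTRUE(all.equal(a$origin, b$origin)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    identical(dim(a$cells), dim(b$cells)) &&
    identical(a$crs, b$crs)
}

# error helper used by every multi-layer operation
check_congruent <- function(grids, what = "layers") {
  stopifnot(length(grids) >= 1)
  ref <- grids[[1]]
  for (i in seq_along(grids)[-1]) {
    if (!grid_congruent(ref, grids[[i]])) {
      stop(what, " are not grid-congruent (layer ", i,
           " differs in origin, cell size, dimensions or CRS)")
    }
  }
  invisible(TRUE)
}

# map coordinates of all cell centers; rows northernmost-first
cell_centers <- function(g) {
  nr <- nrow(g$cells); nc <- ncol(g$cells)
  cs <- g$cell_size
  x <- g$origin[1] + (seq_len(nc) - 0.5) * cs
  y <- g$origin[2] - (seq_len(nr) - 0.5) * cs
  list(x = x, y = y)
}

#' @export
print.pr_grid <- function(x, ...) {
  cat(sprintf("<pr_grid> %d x %d cells, %g m cells (%.2f ha), crs '%s'\n",
              nrow(x$cells), ncol(x$cells), x$cell_size, cell_area_ha(x),
              x$crs))
  cat(sprintf("  origin (%g, %g); %d nodata cells\n",
              x$origin[1], x$origin[2], sum(is.na(x$cells))))
  invisible(x)
}

#' Indicator layer: a grid of risk-class ranks
#'
#' An indicator layer is a \code{pr_grid} whose cells are integer risk ranks
#' 0--3 (\code{NA} = NODATA), tagged with the indicator id it represents.
#'
#' @param g a \code{pr_grid} or matrix of ranks 0--3 / NA.
#' @param indicator_id dotted indicator code (e.g. "3.1.1") or a free label.
#' @param ... passed to \code{pr_grid()} when \code{g} is a bare matrix.
#' @return An object of classes \code{pr_indicator_layer}, \code{pr_grid}.
#' @export
indicator_layer <- function(g, indicator_id = "unnamed", ...) {
  if (is.matrix(g)) g <- pr_grid(g, ...)
  stopifnot(inherits(g, "pr_grid"))
  v <- g$cells
  if (!all(is.na(v) | (v %in% 0:3))) {
    stop("indicator layer cells must be risk ranks 0-3 or NA")
  }
  storage.mode(g$cells) <- "integer"
  g$indicator_id <- indicator_id
  class(g) <- c("pr_indicator_layer", "pr_grid")
  g
}

#' @export
print.pr_indicator_layer <- function(x, ...) {
  cat(sprintf("<pr_indicator_layer> indicator %s\n", x$indicator_id))
  NextMethod()
  tb <- table(factor(risk_label(x$cells), levels = c(risk_levels(), "NODATA")))
  cat("  cells:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Binary mask grid
#'
#' A \code{pr_grid} restricted to cells in \{0, 1, NA\}.
#'
#' @param g a \code{pr_grid} or matrix; logical matrices are converted.
#' @param ... passed to \code{pr_grid()} when \code{g} is a bare matrix.
#' @return An object of classes \code{pr_mask}, \code{pr_grid}.
#' @export
binary_mask <- function(g, ...) {
  if (is.matrix(g)) g <- pr_grid(g, ...)
  stopifnot(inherits(g, "pr_grid"))
  v <- g$cells
  if (is.logical(v)) v <- v * 1L
  if (!all(is.na(v) | v %in% c(0, 1))) {
    stop("mask cells must be 0, 1 or NA")
  }
  g$cells <- matrix(as.integer(v), nrow(g$cells), ncol(g$cells))
  class(g) <- unique(c("pr_mask", class(g)))
  g
}

#' Zone map: categorical grid of analysis zones
#'
#' Zones are integer codes with a code-to-label dictionary (e.g. land-use-plan
#' classes or concession status). Every non-nodata cell must carry a known
#' code.
#'
#' @param g a \code{pr_grid} or matrix of integer zone codes (NA = nodata).
#' @param zone_dict named character vector: names are the integer codes (as
#'   strings), values the human-readable zone labels.
#' @param ... passed to \code{pr_grid()} when \code{g} is a bare matrix.
#' @return An object of classes \code{pr_zone_map}, \code{pr_grid}.
#' @export
zone_map <- function(g, zone_dict, ...) {
  if (is.matrix(g)) g <- pr_grid(g, ...)
  stopifnot(inherits(g, "pr_grid"))
  codes <- suppressWarnings(as.integer(names(zone_dict)))
  if (any(is.na(codes))) stop("zone_dict names must be integer codes")
  v <- g$cells
  unknown <- setdiff(unique(v[!is.na(v)]), codes)
  if (length(unknown)) {
    stop("zone map contains unknown zone code(s): ",
         paste(sort(unknown), collapse = ", "))
  }
  storage.mode(g$cells) <- "integer"
  g$zone_dict <- stats::setNames(as.character(zone_dict), as.character(codes))
  class(g) <- c("pr_zone_map", "pr_grid")
  g
}

#' @export
print.pr_zone_map <- function(x, ...) {
  cat("<pr_zone_map> zones:",
      paste(names(x$zone_dict), x$zone_dict, sep = "=", collapse = ", "), "\n")
  NextMethod()
}
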