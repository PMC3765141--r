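#' Raster I/O: ESRI ASCII grid
#'
#' Grids are exchanged as single-band ESRI ASCII rasters (.asc): a six-line
#' header (\code{ncols}, \code{nrows}, \code{xllcorner}, \code{yllcorner},
#' \code{cellsize}, \code{NODATA_value}) followed by rows of values,
#' northernmost row first. Risk-class layers are stored rank-encoded
#' (0 = LOW ... 3 = VERY_HIGH). The format carries no CRS; the writer emits a
#' plain-text sidecar \code{<file>.crs} with the CRS identifier, which the
#' reader picks up when present.
#'
#' @param path file path (.asc).
#' @param g the \code{pr_grid} (or indicator layer / mask / zone map) to write.
#' @param nodata_value sentinel written for NA cells.
#' @return \code{read_ascii_grid()} returns a \code{pr_grid};
#'   \code{write_ascii_grid()} returns \code{path} invisibly.
#' @export
write_ascii_grid <- function(path, g, nodata_value = -9999) {
  stopifnot(inherits(g, "pr_grid"))
  nr <- nrow(g$cells); nc <- ncol(g$cells)
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", g$origin[1]),
    sprintf("yllcorner %.10g", g$origin[2] - nr * g$cell_size),
    sprintf("cellsize %.10g", g$cell_size),
    sprintf("NODATA_value %.10g", nodata_value)
  )
  v <- g$cells
  v[is.na(v)] <- nodata_value
  rows <- apply(v, 1, function(r) paste(format(r, trim = TRUE,
                                               scientific = FALSE),
                                        collapse = " "))
  writeLines(c(hdr, rows), path)
  writeLines(g$crs, paste0(path, ".crs"))
  invisible(path)
}

#' @rdname write_ascii_grid
#' @param crs CRS identifier to attach when no sidecar file is found.
#' @export
read_ascii_grid <- function(path, crs = NULL) {
  lines <- readLines(path)
  if (length(lines) < 7) stop("not an ESRI ASCII grid: ", path)
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr))) stop("malformed ASCII grid header: ", path)
  nr <- hdr$nrows; nc <- hdr$ncols
  vals <- scan(text = paste(lines[-(1:6)], collapse = " "), quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop("ASCII grid body has ", length(vals), " values, expected ", nr * nc)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA
  sidecar <- paste0(path, ".crs")
  if (is.null(crs)) {
    crs <- if (file.exists(sidecar)) readLines(sidecar, n = 1)
           else "local-projected"
  }
  pr_grid(m,
          origin = c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize),
          cell_size = hdr$cellsize, crs = crs)
}

#' Polygon sets
#'
#' Simple container for vector polygon layers: a list of features, each a
#' list of rings (the first exterior, any others holes; each ring an n x 2
#' matrix of x/y map coordinates, not closed) plus a named \code{properties}
#' list. Point-in-polygon uses the even-odd rule, so holes work without
#' special casing.
#'
#' @param features list of features as described above; a bare ring matrix or
#'   a list of ring matrices is promoted to one feature.
#' @param crs CRS identifier (must match the raster template at rasterize
#'   time).
#' @return An object of class \code{pr_polygons}.
#' @examples
#' sq <- cbind(c(0, 100, 100, 0), c(0, 0, 100, 100))
#' p <- pr_polygons(list(list(rings = list(sq))))
#' @export
pr_polygons <- function(features = list(), crs = "local-projected") {
  if (is.matrix(features)) features <- list(list(rings = list(features)))
  features <- lapply(features, function(f) {
    if (is.matrix(f)) f <- list(rings = list(f))
    if (is.null(f$properties)) f$properties <- list()
    stopifnot(is.list(f$rings), length(f$rings) >= 1)
    f$rings <- lapply(f$rings, function(r) {
      r <- as.matrix(r)
      stopifnot(ncol(r) == 2, nrow(r) >= 3)
      # drop an explicit closing vertex if present
      if (isTRUE(all.equal(r[1, ], r[nrow(r), ]))) r <- r[-nrow(r), , drop = FALSE]
      unname(r)
    })
    f
  })
  structure(list(features = features, crs = as.character(crs)),
            class = "pr_polygons")
}

#' @export
print.pr_polygons <- function(x, ...) {
  cat(sprintf("<pr_polygons> %d feature(s), crs '%s'\n",
              length(x$features), x$crs), ...)
  invisible(x)
}

#' @export
length.pr_polygons <- function(x) length(x$features)

#' GeoJSON I/O for polygon sets
#'
#' Writes/reads a GeoJSON FeatureCollection of Polygon/MultiPolygon features.
#' The CRS identifier travels in the (GeoJSON-legacy) top-level \code{crs}
#' member so round-trips preserve it.
#'
#' @param polys a \code{pr_polygons}.
#' @param path file path (.geojson).
#' @return \code{read_geojson()} returns a \code{pr_polygons};
#'   \code{write_geojson()} returns \code{path} invisibly.
#' @export
write_geojson <- function(path, polys) {
  stopifnot(inherits(polys, "pr_polygons"))
  feats <- lapply(polys$features, function(f) {
    rings <- lapply(f$rings, function(r) {
      r <- rbind(r, r[1, ])                       # GeoJSON rings are closed
      lapply(seq_len(nrow(r)), function(i) as.numeric(r[i, ]))
    })
    list(type = "Feature",
         properties = if (length(f$properties)) f$properties
                      else stats::setNames(list(), character()),
         geometry = list(type = "Polygon", coordinates = rings))
  })
  doc <- list(type = "FeatureCollection",
              crs = list(type = "name",
                         properties = list(name = polys$crs)),
              features = feats)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' @rdname write_geojson
#' @export
read_geojson <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection: ", path)
  }
  crs <- tryCatch(doc$crs$properties$name, error = function(e) NULL)
  if (is.null(crs)) crs <- "local-projected"
  ring_to_matrix <- function(ring) {
    m <- do.call(rbind, lapply(ring, function(pt) as.numeric(unlist(pt)[1:2])))
    m
  }
  feats <- list()
  for (f in doc$features) {
    geom <- f$geometry
    props <- if (length(f$properties)) lapply(f$properties, identity) else list()
    if (identical(geom$type, "Polygon")) {
      feats[[length(feats) + 1]] <-
        list(rings = lapply(geom$coordinates, ring_to_matrix),
             properties = props)
    } else if (identical(geom$type, "MultiPolygon")) {
      for (poly in geom$coordinates) {
        feats[[length(feats) + 1]] <-
          list(rings = lapply(poly, ring_to_matrix), properties = props)
      }
    } else {
      stop("unsupported geometry type: ", geom$type)
    }
  }
  pr_polygons(feats, crs = crs)
}
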