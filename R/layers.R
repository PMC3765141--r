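#' Rasterize polygons onto a template grid
#'
#' A cell becomes 1 iff its center falls inside any polygon of the set
#' (even-odd rule, so holes are excluded). Georeferencing is copied from the
#' template. Polygons and template must share the CRS; no reprojection is
#' attempted.
#'
#' @param polygons a \code{pr_polygons}.
#' @param template a \code{pr_grid} supplying geometry.
#' @return A \code{pr_mask} (binary grid).
#' @export
rasterize_polygons <- function(polygons, template) {
  stopifnot(inherits(polygons, "pr_polygons"), inherits(template, "pr_grid"))
  if (!identical(polygons$crs, template$crs)) {
    stop("CRS mismatch: polygons '", polygons$crs, "' vs template '",
         template$crs, "' (no reprojection supported)")
  }
  ctr <- cell_centers(template)
  pts <- cbind(rep(ctr$x, each = length(ctr$y)),
               rep(ctr$y, times = length(ctr$x)))
  # pts is in column-major cell order (rows vary fastest)
  inside <- rep(FALSE, nrow(pts))
  for (f in polygons$features) {
    bnd <- do.call(rbind, lapply(f$rings, function(r)
      rbind(r, r[1, ], c(NA, NA))))
    bnd <- bnd[-nrow(bnd), , drop = FALSE]      # drop trailing NA row
    inside <- inside | mgcv::in.out(bnd, pts)
  }
  m <- matrix(as.integer(inside), nrow = nrow(template$cells),
              ncol = ncol(template$cells))
  binary_mask(pr_grid(m, origin = template$origin,
                      cell_size = template$cell_size, crs = template$crs))
}

#' Euclidean distance buffer on a binary mask
#'
#' Expands a mask: an output cell is 1 iff its center lies within
#' \code{distance_m} (Euclidean, center to center) of any 1-cell of the
#' input. Input 1-cells are always included; \code{distance_m = 0} is the
#' identity. Implemented as dilation with the exact set of integer cell
#' offsets inside the radius. NODATA cells act as 0 for the geometry and
#' stay NODATA in the output.
#'
#' @param mask a \code{pr_mask}.
#' @param distance_m buffer distance in metres (>= 0).
#' @return A \code{pr_mask}.
#' @export
distance_buffer <- function(mask, distance_m) {
  stopifnot(inherits(mask, "pr_grid"))
  if (!is.numeric(distance_m) || length(distance_m) != 1 || distance_m < 0) {
    stop("distance_m must be a single non-negative number of metres")
  }
  src <- mask$cells
  na_cells <- is.na(src)
  src[na_cells] <- 0L
  r_cells <- distance_m / mask$cell_size
  rmax <- floor(r_cells + 1e-9)
  nr <- nrow(src); nc <- ncol(src)
  out <- matrix(FALSE, nr, nc)
  for (di in -rmax:rmax) {
    for (dj in -rmax:rmax) {
      if (di * di + dj * dj > r_cells^2 + 1e-9) next
      # OR the mask shifted by (di, dj) into out
      si <- max(1, 1 - di):min(nr, nr - di)
      sj <- max(1, 1 - dj):min(nc, nc - dj)
      out[si + di, sj + dj] <- out[si + di, sj + dj] | (src[si, sj] == 1L)
    }
  }
  res <- matrix(as.integer(out), nr, nc)
  res[na_cells] <- NA_integer_
  binary_mask(pr_grid(res, origin = mask$origin, cell_size = mask$cell_size,
                      crs = mask$crs))
}

#' Connected components of a binary mask
#'
#' Labels maximal connected regions of 1-cells (4- or 8-connectivity) and
#' reports each region's area in hectares. Labels are assigned 1, 2, ... in
#' row-major order of each region's first cell, so labelling is
#' deterministic.
#'
#' @param mask a \code{pr_mask}.
#' @param connectivity 4 (edge-adjacent) or 8 (edge- or corner-adjacent).
#' @return A list of class \code{pr_labeled_regions}: \code{labels} (a
#'   \code{pr_grid} of integer labels, 0 = background) and \code{regions}
#'   (data.frame with \code{label}, \code{n_cells}, \code{area_ha}).
#' @export
connected_components <- function(mask, connectivity = 8) {
  stopifnot(inherits(mask, "pr_grid"), connectivity %in% c(4, 8))
  m <- mask$cells
  nr <- nrow(m); nc <- ncol(m)
  on <- which(!is.na(m) & m == 1L)           # column-major indices
  lab <- matrix(0L, nr, nc)
  regions <- data.frame(label = integer(), n_cells = integer(),
                        area_ha = numeric())
  if (length(on)) {
    ri <- (on - 1L) %% nr + 1L
    ci <- (on - 1L) %/% nr + 1L
    key <- function(r, c) (c - 1L) * nr + r
    offs <- if (connectivity == 4) {
      cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
    } else {
      cbind(rep(c(-1L, 0L, 1L), times = 3), rep(c(-1L, 0L, 1L), each = 3))
    }
    offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), , drop = FALSE]
    edges <- NULL
    onset <- logical(nr * nc); onset[on] <- TRUE
    for (k in seq_len(nrow(offs))) {
      r2 <- ri + offs[k, 1]; c2 <- ci + offs[k, 2]
      ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
      ok[ok] <- onset[key(r2[ok], c2[ok])]
      if (any(ok)) edges <- rbind(edges, cbind(on[ok], key(r2[ok], c2[ok])))
    }
    idx <- match(on, on)                     # identity; vertex ids 1..n
    g <- igraph::make_empty_graph(n = length(on), directed = FALSE)
    if (!is.null(edges)) {
      e <- cbind(match(edges[, 1], on), match(edges[, 2], on))
      g <- igraph::add_edges(g, t(e))
    }
    comp <- igraph::components(g)$membership
    # relabel so that region 1 is the one whose first cell comes first in
    # row-major order
    rowmaj <- (ri - 1L) * nc + ci
    first_rowmaj <- tapply(rowmaj, comp, min)
    new_id <- match(comp, order(first_rowmaj) |>
                      (\(o) as.integer(names(first_rowmaj))[o])())
    lab[on] <- new_id
    cnt <- tabulate(new_id)
    regions <- data.frame(label = seq_along(cnt), n_cells = cnt,
                          area_ha = cnt * cell_area_ha(mask))
  }
  lab_grid <- pr_grid(lab, origin = mask$origin, cell_size = mask$cell_size,
                      crs = mask$crs)
  lab_grid$cells[is.na(mask$cells)] <- NA_integer_
  structure(list(labels = lab_grid, regions = regions,
                 connectivity = connectivity),
            class = "pr_labeled_regions")
}

#' @export
print.pr_labeled_regions <- function(x, ...) {
  cat(sprintf("<pr_labeled_regions> %d region(s), connectivity %d\n",
              nrow(x$regions), x$connectivity))
  if (nrow(x$regions)) print(utils::head(x$regions, 10))
  invisible(x)
}

#' Protection-area indicator layer (formal protection, HCV 1.1)
#'
#' Protected cells are VERY_HIGH risk; cells within \code{buffer_m} of a
#' protected cell (but not protected themselves) are MEDIUM (the 1 km buffer
#' zone); everything else is LOW (no overlap with protected areas or their
#' buffers).
#'
#' @param protected_mask \code{pr_mask} of protected / conservation areas.
#' @param buffer_m buffer distance in metres (default 1000).
#' @return A \code{pr_indicator_layer} with indicator id "1.1.1".
#' @export
build_protection_layer <- function(protected_mask, buffer_m = 1000) {
  stopifnot(inherits(protected_mask, "pr_grid"))
  buf <- distance_buffer(protected_mask, buffer_m)
  p <- protected_mask$cells
  b <- buf$cells
  rk <- matrix(0L, nrow(p), ncol(p))
  rk[b == 1L] <- 1L                          # buffer zone -> MEDIUM
  rk[p == 1L] <- 3L                          # protected -> VERY_HIGH
  rk[is.na(p)] <- NA_integer_
  indicator_layer(pr_grid(rk, origin = protected_mask$origin,
                          cell_size = protected_mask$cell_size,
                          crs = protected_mask$crs),
                  indicator_id = "1.1.1")
}

#' Forest-block / ecosystem indicator layer (HCV 2 & 3)
#'
#' Per-cell class is the ordinal maximum of three tiers: MEDIUM where the
#' cell belongs to a contiguous forest block larger than \code{min_block_ha}
#' or lies within \code{buffer_m} of one; HIGH where two or more ecotone
#' regions meet or an endangered ecosystem is present; VERY_HIGH on rare
#' ecosystems (karst class 1, peat, freshwater swamp, mangrove, heath or
#' cloud forest); LOW elsewhere. Block area is measured before buffering
#' and the size test is strict (a block of exactly \code{min_block_ha} does
#' not qualify); the buffer ring inherits MEDIUM but does not enlarge the
#' block for the threshold test.
#'
#' @param forest_mask \code{pr_mask} of forest cover.
#' @param endangered_ecosystem_mask \code{pr_mask} of endangered ecosystems.
#' @param ecotone_count \code{pr_grid} of the number of ecotone regions
#'   meeting at each cell.
#' @param rare_ecosystem_mask \code{pr_mask} of rare ecosystems.
#' @param min_block_ha minimum contiguous forest-block area (strict, ha).
#' @param buffer_m buffer distance around qualifying blocks (metres).
#' @param connectivity block connectivity, 8 by default (diagonal forest
#'   continuity does not split a block).
#' @return A \code{pr_indicator_layer} with indicator id "1.1.3".
#' @export
build_forest_block_layer <- function(forest_mask, endangered_ecosystem_mask,
                                     ecotone_count, rare_ecosystem_mask,
                                     min_block_ha = 20000, buffer_m = 3000,
                                     connectivity = 8) {
  check_congruent(list(forest_mask, endangered_ecosystem_mask, ecotone_count,
                       rare_ecosystem_mask), "forest-block inputs")
  cc <- connected_components(forest_mask, connectivity)
  big <- cc$regions$label[cc$regions$area_ha > min_block_ha]
  big_mask <- binary_mask(pr_grid(
    matrix(as.integer(cc$labels$cells %in% big),
           nrow(forest_mask$cells), ncol(forest_mask$cells)),
    origin = forest_mask$origin, cell_size = forest_mask$cell_size,
    crs = forest_mask$crs))
  buffered <- distance_buffer(big_mask, buffer_m)
  rk <- matrix(0L, nrow(forest_mask$cells), ncol(forest_mask$cells))
  rk[buffered$cells == 1L] <- 1L
  eco <- ecotone_count$cells
  end <- endangered_ecosystem_mask$cells
  rk[(!is.na(eco) & eco >= 2) | (!is.na(end) & end == 1L)] <-
    pmax(rk[(!is.na(eco) & eco >= 2) | (!is.na(end) & end == 1L)], 2L)
  rare <- rare_ecosystem_mask$cells
  rk[!is.na(rare) & rare == 1L] <- 3L
  rk[is.na(forest_mask$cells)] <- NA_integer_
  indicator_layer(pr_grid(rk, origin = forest_mask$origin,
                          cell_size = forest_mask$cell_size,
                          crs = forest_mask$crs),
                  indicator_id = "1.1.3")
}

#' Species indicator layer (protected and endangered species, HCV 1.2-1.4)
#'
#' Per-cell ordinal maximum of three tiers: MEDIUM on overlap with a species
#' distribution, HIGH on overlap with habitat, VERY_HIGH on critical sites
#' (breeding grounds, nesting places, key temporal habitats); LOW where none
#' apply.
#'
#' @param distribution_mask,habitat_mask,critical_site_mask congruent
#'   \code{pr_mask}s for the three tiers.
#' @return A \code{pr_indicator_layer} with indicator id "1.1.2".
#' @export
build_species_layer <- function(distribution_mask, habitat_mask,
                                critical_site_mask) {
  check_congruent(list(distribution_mask, habitat_mask, critical_site_mask),
                  "species-layer inputs")
  d <- distribution_mask$cells; h <- habitat_mask$cells
  s <- critical_site_mask$cells
  rk <- matrix(0L, nrow(d), ncol(d))
  rk[!is.na(d) & d == 1L] <- 1L
  rk[!is.na(h) & h == 1L] <- 2L
  rk[!is.na(s) & s == 1L] <- 3L
  rk[is.na(d) & is.na(h) & is.na(s)] <- NA_integer_
  indicator_layer(pr_grid(rk, origin = distribution_mask$origin,
                          cell_size = distribution_mask$cell_size,
                          crs = distribution_mask$crs),
                  indicator_id = "1.1.2")
}
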