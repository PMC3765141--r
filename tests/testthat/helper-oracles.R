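# Brute-force reference implementations, kept deliberately independent of
# the package's algorithms: plain loops and from-first-principles geometry.

random_mask <- function(nr, nc, p = 0.3, cell_size = 100) {
  binary_mask(matrix(as.integer(stats::runif(nr * nc) < p), nr, nc),
              cell_size = cell_size)
}

random_layer <- function(nr, nc, cell_size = 100, p_na = 0) {
  v <- sample(0:3, nr * nc, replace = TRUE)
  if (p_na > 0) v[stats::runif(nr * nc) < p_na] <- NA
  indicator_layer(matrix(as.integer(v), nr, nc), cell_size = cell_size)
}

# per-cell loop classification
bf_classify_grid <- function(table, grid) {
  out <- grid$cells
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(ncol(out))) {
      lab <- classify_value(table, grid$cells[i, j])
      out[i, j] <- if (lab == "NODATA") NA else risk_rank(lab)
    }
  }
  out
}

# all-pairs center-distance buffer
bf_distance_buffer <- function(mask, distance_m) {
  m <- mask$cells
  nr <- nrow(m); nc <- ncol(m)
  cs <- mask$cell_size
  ones <- which(!is.na(m) & m == 1, arr.ind = TRUE)
  out <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (nrow(ones) == 0) next
      d <- sqrt(((ones[, 1] - i) * cs)^2 + ((ones[, 2] - j) * cs)^2)
      if (any(d <= distance_m + 1e-9)) out[i, j] <- 1L
    }
  }
  out[is.na(m)] <- NA_integer_
  out
}

# iterative flood fill (stack-based, so deep regions don't recurse)
bf_flood_fill <- function(mask, connectivity) {
  m <- mask$cells
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    ll <- list()
    for (a in -1:1) for (b in -1:1) if (a || b) ll <- c(ll, list(c(a, b)))
    ll
  }
  nxt <- 0L
  # scan in row-major order so labels match the package's convention
  for (si in seq_len(nr)) for (sj in seq_len(nc)) {
    if (is.na(m[si, sj]) || m[si, sj] != 1 || lab[si, sj] != 0) next
    nxt <- nxt + 1L
    stack <- list(c(si, sj))
    lab[si, sj] <- nxt
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (o in offs) {
        r <- cur[1] + o[1]; c <- cur[2] + o[2]
        if (r < 1 || r > nr || c < 1 || c > nc) next
        if (!is.na(m[r, c]) && m[r, c] == 1 && lab[r, c] == 0) {
          lab[r, c] <- nxt
          stack[[length(stack) + 1]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# even-odd ray casting, one point at a time
bf_point_in_polygons <- function(polys, px, py) {
  inside_ring <- function(ring, x, y) {
    n <- nrow(ring)
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      xi <- ring[i, 1]; yi <- ring[i, 2]
      xj <- ring[j, 1]; yj <- ring[j, 2]
      if ((yi > y) != (yj > y) &&
          x < (xj - xi) * (y - yi) / (yj - yi) + xi) {
        inside <- !inside
      }
      j <- i
    }
    inside
  }
  any(vapply(polys$features, function(f) {
    crossings <- vapply(f$rings, inside_ring, logical(1), x = px, y = py)
    sum(crossings) %% 2 == 1
  }, logical(1)))
}

bf_rasterize <- function(polys, template) {
  ctr <- cell_centers(template)
  out <- matrix(0L, nrow(template$cells), ncol(template$cells))
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(ncol(out))) {
      out[i, j] <- as.integer(bf_point_in_polygons(polys, ctr$x[j], ctr$y[i]))
    }
  }
  out
}

# per-cell maximum with both nodata policies
bf_combine <- function(layers, policy = "ignore") {
  nr <- nrow(layers[[1]]$cells); nc <- ncol(layers[[1]]$cells)
  out <- matrix(NA_integer_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    v <- vapply(layers, function(l) l$cells[i, j], integer(1))
    out[i, j] <- if (policy == "ignore") {
      if (all(is.na(v))) NA_integer_ else max(v, na.rm = TRUE)
    } else {
      if (any(is.na(v))) NA_integer_ else max(v)
    }
  }
  out
}

bf_class_counts <- function(layer) {
  cnt <- c(0, 0, 0, 0)
  for (v in as.vector(layer$cells)) {
    if (!is.na(v)) cnt[v + 1] <- cnt[v + 1] + 1
  }
  cnt
}

bf_cross_counts <- function(rim, zones) {
  codes <- sort(as.integer(names(zones$zone_dict)))
  out <- matrix(0, length(codes), 4, dimnames = list(codes, NULL))
  for (i in seq_len(nrow(rim$cells))) for (j in seq_len(ncol(rim$cells))) {
    z <- zones$cells[i, j]; r <- rim$cells[i, j]
    if (!is.na(z) && !is.na(r)) {
      out[as.character(z), r + 1] <- out[as.character(z), r + 1] + 1
    }
  }
  out
}
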