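test_that("rasterize covers the full template for a covering polygon and is empty for none", {
  tpl <- pr_grid(matrix(0, 5, 5), origin = c(0, 500), cell_size = 100)
  big <- cbind(c(-10, 510, 510, -10), c(-10, -10, 510, 510))
  expect_true(all(rasterize_polygons(pr_polygons(big), tpl)$cells == 1L))
  expect_true(all(rasterize_polygons(pr_polygons(), tpl)$cells == 0L))
  expect_error(rasterize_polygons(pr_polygons(big, crs = "other"), tpl),
               "CRS mismatch")
})

test_that("rasterize matches brute-force point-in-polygon on random triangles", {
  set.seed(2024)
  tpl <- pr_grid(matrix(0, 50, 50), origin = c(0, 5000), cell_size = 100)
  for (rep in 1:3) {
    tris <- lapply(1:4, function(i) {
      m <- matrix(stats::runif(6, 0, 5000), 3, 2)
      list(rings = list(m))
    })
    p <- pr_polygons(tris)
    expect_equal(rasterize_polygons(p, tpl)$cells, bf_rasterize(p, tpl))
  }
})

test_that("distance buffer: identity at 0, 4-neighbour cross at one cell size", {
  m <- matrix(0L, 5, 5); m[3, 3] <- 1L
  mask <- binary_mask(m, cell_size = 1000)
  expect_equal(distance_buffer(mask, 0)$cells, m)
  b <- distance_buffer(mask, 1000)$cells
  cross <- m; cross[2, 3] <- cross[4, 3] <- cross[3, 2] <- cross[3, 4] <- 1L
  expect_equal(b, cross)          # diagonal centers at sqrt(2) km excluded
  expect_error(distance_buffer(mask, -5), "non-negative")
})

test_that("distance buffer is monotone in distance and matches brute force", {
  set.seed(31)
  for (rep in 1:5) {
    mask <- random_mask(30, 30, p = 0.08, cell_size = 500)
    prev <- mask$cells
    for (d in c(500, 1500, 2500)) {
      b <- distance_buffer(mask, d)
      expect_equal(b$cells, bf_distance_buffer(mask, d))
      expect_true(all(b$cells[prev == 1L] == 1L))   # superset of smaller
      prev <- b$cells
    }
  }
})

test_that("connected components: connectivity semantics and area arithmetic", {
  m <- matrix(0L, 3, 3); m[1, 1] <- 1L; m[2, 2] <- 1L
  expect_equal(nrow(connected_components(binary_mask(m), 4)$regions), 2)
  expect_equal(nrow(connected_components(binary_mask(m), 8)$regions), 1)
  all1 <- connected_components(binary_mask(matrix(1L, 10, 10),
                                           cell_size = 1000), 8)
  expect_equal(all1$regions$area_ha, 10000)
  none <- connected_components(binary_mask(matrix(0L, 4, 4)), 8)
  expect_equal(nrow(none$regions), 0)
  expect_true(all(none$labels$cells == 0L))
})

test_that("connected components match flood fill; region areas sum to the mask area", {
  set.seed(7)
  for (rep in 1:6) {
    conn <- if (rep %% 2) 4 else 8
    mask <- random_mask(40, 40, p = 0.45, cell_size = 200)
    cc <- connected_components(mask, conn)
    expect_equal(cc$labels$cells, bf_flood_fill(mask, conn))
    expect_equal(sum(cc$regions$area_ha),
                 sum(mask$cells == 1L, na.rm = TRUE) * cell_area_ha(mask))
    expect_equal(cc$regions$label, seq_len(nrow(cc$regions)))
  }
})

test_that("protection layer tiers: protected VERY_HIGH, 1 km ring MEDIUM, rest LOW", {
  empty <- binary_mask(matrix(0L, 6, 6), cell_size = 1000)
  expect_true(all(build_protection_layer(empty)$cells == 0L))
  m <- matrix(0L, 5, 5); m[3, 3] <- 1L
  lyr <- build_protection_layer(binary_mask(m, cell_size = 1000),
                                buffer_m = 1000)
  expect_equal(lyr$cells[3, 3], 3L)
  expect_equal(lyr$cells[2, 3], 1L)
  expect_equal(lyr$cells[2, 2], 0L)
  expect_equal(lyr$indicator_id, "1.1.1")
  # class-count identities on random masks
  set.seed(12)
  for (rep in 1:4) {
    mask <- random_mask(25, 25, p = 0.1, cell_size = 500)
    lyr <- build_protection_layer(mask, buffer_m = 1000)
    expect_equal(sum(lyr$cells == 3L), sum(mask$cells == 1L))
    buf <- bf_distance_buffer(mask, 1000)
    want <- ifelse(mask$cells == 1L, 3L, ifelse(buf == 1L, 1L, 0L))
    expect_equal(lyr$cells, want)
  }
})

test_that("forest-block layer: strict 20,000 ha threshold and 3 km buffer ring", {
  nr <- 60; nc <- 60; cs <- 1000                    # 1000 m cells: 100 ha each
  zero <- binary_mask(matrix(0L, nr, nc), cell_size = cs)
  zcount <- pr_grid(matrix(0, nr, nc), cell_size = cs)
  # block of exactly 200 cells = 20,000 ha: below the strict threshold
  f <- matrix(0L, nr, nc); f[1:10, 1:20] <- 1L
  lyr <- build_forest_block_layer(binary_mask(f, cell_size = cs), zero,
                                  zcount, zero)
  expect_true(all(lyr$cells == 0L))
  # 250 cells = 25,000 ha: block plus 3 km ring become MEDIUM
  f2 <- matrix(0L, nr, nc); f2[1:10, 1:25] <- 1L
  lyr2 <- build_forest_block_layer(binary_mask(f2, cell_size = cs), zero,
                                   zcount, zero)
  expect_true(all(lyr2$cells[f2 == 1L] == 1L))
  expect_equal(lyr2$cells[13, 1], 1L)               # 3 cells below the block
  expect_equal(lyr2$cells[14, 1], 0L)               # 4 cells: outside 3 km
  # ordinal maximum: rare ecosystem overrules ecotone count
  eco <- pr_grid(matrix(2, nr, nc), cell_size = cs)
  rare <- binary_mask(matrix(1L, nr, nc), cell_size = cs)
  lyr3 <- build_forest_block_layer(binary_mask(f2, cell_size = cs), zero,
                                   eco, rare)
  expect_true(all(lyr3$cells == 3L))
  expect_error(build_forest_block_layer(
    binary_mask(matrix(0L, 2, 2)), zero, zcount, zero), "congruent")
})

test_that("species layer is the ordinal maximum of its three tiers", {
  z <- binary_mask(matrix(0L, 4, 4))
  expect_true(all(build_species_layer(z, z, z)$cells == 0L))
  h <- binary_mask(matrix(1L, 4, 4))
  expect_true(all(build_species_layer(z, h, z)$cells == 2L))
  d <- binary_mask(matrix(1L, 4, 4))
  s <- binary_mask(matrix(1L, 4, 4))
  expect_true(all(build_species_layer(d, z, s)$cells == 3L))
  set.seed(5)
  dm <- random_mask(20, 20, 0.3); hm <- random_mask(20, 20, 0.3)
  hm$origin <- dm$origin; hm$cell_size <- dm$cell_size
  sm <- random_mask(20, 20, 0.3)
  lyr <- build_species_layer(dm, hm, sm)
  want <- pmax(dm$cells * 1L, hm$cells * 2L, sm$cells * 3L)
  expect_equal(lyr$cells, want)
})
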