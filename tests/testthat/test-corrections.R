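# Linearity and uniformity corrections.

test_that("a perfect reconstruction gives an identity linearity map", {
  grid <- calibration_grid(n_side = 5, spacing = 10)
  rec <- grid[rep(seq_len(nrow(grid)), each = 4), ]
  map <- build_linearity_map(grid, rec)
  expect_true(all(map$dx == 0) && all(map$dy == 0))
  pos <- cbind(c(-12.3, 0, 7.7), c(3, -8, 19))
  expect_equal(apply_linearity(pos, map), pos)
})

test_that("a uniform injected bias is undone exactly", {
  grid <- calibration_grid(n_side = 5, spacing = 10)
  rec <- grid[rep(seq_len(nrow(grid)), each = 3), ]
  rec$x <- rec$x + 1
  rec$y <- rec$y - 0.4
  map <- build_linearity_map(grid, rec)
  truth <- cbind(c(-15, 2.5, 11), c(-11, 0, 16))
  shifted <- truth + matrix(rep(c(1, -0.4), each = 3), ncol = 2)
  expect_equal(apply_linearity(shifted, map), truth, tolerance = 1e-12)
})

test_that("the interpolated correction is exact on lattice nodes", {
  grid <- calibration_grid(n_side = 5, spacing = 10)
  set.seed(60)
  rec <- grid
  rec$x <- grid$x + rnorm(nrow(grid), 0, 0.5)
  rec$y <- grid$y + rnorm(nrow(grid), 0, 0.5)
  map <- build_linearity_map(grid, rec)
  node <- 13
  corrected <- apply_linearity(cbind(grid$x[node], grid$y[node]), map)
  expect_equal(drop(corrected),
               c(2 * grid$x[node] - rec$x[node],
                 2 * grid$y[node] - rec$y[node]), tolerance = 1e-12)
})

test_that("missing calibration nodes are reported", {
  grid <- calibration_grid(n_side = 3, spacing = 10)
  rec <- grid[-4, ]
  expect_error(build_linearity_map(grid, rec), "4")
})

test_that("an ideal flat field yields a map of ones within shot noise", {
  set.seed(61)
  pos <- cbind(runif(60000, -58.5, 58.5), runif(60000, -58.5, 58.5))
  umap <- build_uniformity_map(pos)
  n_per_bin <- 60000 / length(umap$map)
  expect_equal(mean(umap$map), 1, tolerance = 0.01)
  expect_lt(sd(umap$map), 3 / sqrt(n_per_bin))
  expect_equal(umap$clamped_fraction, 0)
})

test_that("a known sensitivity dip is inverted and flattens the image", {
  set.seed(62)
  n <- 150000
  pos <- cbind(runif(n, -58.5, 58.5), runif(n, -58.5, 58.5))
  # 20% dip in a block
  dip <- pos[, 1] > 10 & pos[, 1] < 36 & pos[, 2] > 10 & pos[, 2] < 36
  keep <- !dip | runif(n) > 0.2
  pos <- pos[keep, ]
  umap <- build_uniformity_map(pos)
  in_dip <- umap$xmid > 12 & umap$xmid < 34
  expect_equal(mean(umap$map[in_dip, umap$ymid > 12 & umap$ymid < 34]),
               1 / 0.8 * mean(umap$map[!in_dip, ]), tolerance = 0.05)
  img <- make_image(pos, 6.5, c(-58.5, 58.5, -58.5, 58.5))
  cov_raw <- image_cov(img)
  corrected <- apply_uniformity(img, umap)
  expect_lt(image_cov(corrected), cov_raw)
})

test_that("both corrections restore the calibration nodes within 0.5 mm", {
  pl <- get_pipeline(1, "room")
  grid <- pl$grid
  interior <- abs(grid$x) <= 45 & abs(grid$y) <= 45
  set.seed(63)
  idx <- which(interior)[seq(1, sum(interior), by = 7)]
  for (j in idx) {
    ds <- lasipcam:::simulate_group_dataset(
      pl$cfg, pl$tiling, source_spec("point", x = grid$x[j], y = grid$y[j]),
      30)
    rc <- reconstruct_events(ds$charges, pl$tiling, pl$lrf, pl$recon)
    cc <- apply_linearity(cbind(rc$x, rc$y), pl$linearity)
    expect_lt(abs(mean(cc[, 1]) - grid$x[j]), 0.5)
    expect_lt(abs(mean(cc[, 2]) - grid$y[j]), 0.5)
  }
})

test_that("linearity correction conserves event counts in images", {
  pl <- get_pipeline(1, "room")
  set.seed(64)
  pos <- cbind(runif(5000, -40, 40), runif(5000, -40, 40))
  cc <- apply_linearity(pos, pl$linearity)
  expect_equal(nrow(cc), nrow(pos))
  img <- make_image(cc, 1, c(-58.5, 58.5, -58.5, 58.5))
  expect_equal(sum(img$counts), sum(abs(cc[, 1]) < 58.5 & abs(cc[, 2]) < 58.5),
               tolerance = 0.001)
})
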