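# Light-response-function sampling and bell fits.

test_that("normalised charge samples sum to one over pixels at every node", {
  cfg <- std_optics()
  tl <- get_tiling(1)
  grid <- calibration_grid(n_side = 3, spacing = 13)
  set.seed(40)
  s <- collect_lrf_samples(cfg, tl, grid, events_per_point = 50)
  expect_true(all(abs(colSums(s$mean) - 1) < 1e-6))
  expect_true(all(s$mean >= 0 & s$mean <= 1))
  # a pixel far from the beam sees almost nothing
  far <- which.min((tl$groups$cx - 100)^2 + (tl$groups$cy - 100)^2)
  expect_lt(max(s$mean[far, ]), 0.01)
  # the beam on a pixel centre makes that pixel the brightest
  j <- which(grid$x == 0 & grid$y == 0)
  under <- which.min((tl$groups$cx - 0)^2 + (tl$groups$cy - 0)^2)
  near0 <- which(abs(tl$groups$cx) < 15 & abs(tl$groups$cy) < 15)
  expect_equal(which.max(s$mean[near0, j]), which(near0 == under))
})

test_that("bell parameters are recovered from synthetic samples within 5%", {
  truth <- c(a = 0.5, b = 12, c = 1.3, d = 1, e = -2)
  grid <- calibration_grid()
  f <- truth["a"] /
    (1 + (((grid$x - truth["d"])^2 + (grid$y - truth["e"])^2) /
            truth["b"]^2)^truth["c"])
  set.seed(41)
  mn <- matrix(f * (1 + rnorm(length(f), 0, 0.01)), nrow = 1)
  se <- matrix(0.01 * pmax(f, 1e-4), nrow = 1)
  samples <- structure(list(mean = mn, se = se, grid = grid),
                       class = "lrf_samples")
  # minimal single-group tiling shim
  tl <- list(n_groups = 1L, n_sipm = 9L,
             groups = data.frame(gid = 1L, cx = 0, cy = 0, partial = FALSE),
             layout = list(pitch = 6.25))
  fit <- fit_bell(samples, tl, coverage_margin = 100)
  expect_true(fit$ok[1])
  for (p in names(truth))
    expect_lt(abs(fit$params[1, p] - truth[[p]]) / abs(truth[[p]]), 0.05)
})

test_that("fitted bells peak at their centre and are radially symmetric", {
  tl <- get_tiling(1)
  lrf <- synthetic_lrf(tl)
  g <- 67
  d <- lrf$params[g, "d"]; e <- lrf$params[g, "e"]
  pk <- evaluate_lrf(lrf, g, d, e)
  expect_equal(pk, unname(lrf$params[g, "a"]))
  u <- c(1.3, 4.7, 9.1)
  expect_equal(evaluate_lrf(lrf, g, d + u, rep(e, 3)),
               evaluate_lrf(lrf, g, d - u, rep(e, 3)))
  expect_true(all(evaluate_lrf(lrf, g, d + u, rep(e, 3)) < pk))
})

test_that("pipeline LRF centres sit within half a pitch of the pixel centroids", {
  pl <- get_pipeline(1, "room")
  ok <- which(pl$lrf$ok & !pl$tiling$groups$partial &
                abs(pl$tiling$groups$cx) < 50 &
                abs(pl$tiling$groups$cy) < 50)
  half_pitch <- 18.75 / 2
  dd <- sqrt((pl$lrf$params[ok, "d"] - pl$tiling$groups$cx[ok])^2 +
               (pl$lrf$params[ok, "e"] - pl$tiling$groups$cy[ok])^2)
  expect_true(all(dd < half_pitch))
})

test_that("fitted LRFs reproduce held-out calibration samples within the bell family's accuracy", {
  # The five-parameter bell smooths the true pixel response (flat-topped
  # from aperture integration, with heavier-than-bell kernel tails), so
  # held-out samples reproduce to ~15-25% relative, not exactly.
  cfg <- std_optics()
  tl <- get_tiling(1)
  # held-out nodes offset from the pipeline's calibration lattice
  grid <- calibration_grid(n_side = 5, spacing = 9.75)
  set.seed(43)
  s <- collect_lrf_samples(cfg, tl, grid, events_per_point = 80)
  pl <- get_pipeline(1, "room")
  rel <- c()
  for (j in seq_len(nrow(grid))) {
    gsel <- which(pl$lrf$ok & s$mean[, j] > 0.05 * max(s$mean[, j]))
    if (!length(gsel)) next
    pred <- vapply(gsel, function(g)
      evaluate_lrf(pl$lrf, g, grid$x[j], grid$y[j]), 0)
    rel <- c(rel, abs(pred - s$mean[gsel, j]) / s$mean[gsel, j])
  }
  expect_lt(median(rel), 0.25)
  expect_lt(unname(quantile(rel, 0.95)), 0.35)
})

test_that("LRF tables round-trip through the text serialisation", {
  pl <- get_pipeline(1, "room")
  path <- tempfile(fileext = ".tsv")
  write_lrf(pl$lrf, path)
  lrf2 <- read_lrf(path)
  expect_equal(lrf2$params, pl$lrf$params, tolerance = 1e-9)
  expect_equal(lrf2$ok, pl$lrf$ok)
})
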