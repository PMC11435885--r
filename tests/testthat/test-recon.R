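# Maximum-likelihood positioning.

test_that("NLL is minimised where charges are proportional to the LRFs", {
  tl <- get_tiling(1)
  lrf <- synthetic_lrf(tl)
  x0 <- 5; y0 <- -2
  used <- nearest_groups(tl, 67, 21)
  q <- 1000 * evaluate_lrf_set(lrf, used, x0, y0)
  v0 <- neg_log_likelihood(q, lrf, used, x0, y0)
  for (dx in c(-3, -0.5, 0.5, 3))
    for (dy in c(-2, 0, 2))
      if (dx != 0 || dy != 0)
        expect_gt(neg_log_likelihood(q, lrf, used, x0 + dx, y0 + dy), v0)
})

test_that("NLL over a single pixel carries no position information", {
  tl <- get_tiling(1)
  lrf <- synthetic_lrf(tl)
  v <- vapply(seq(-20, 20, by = 5), function(x)
    neg_log_likelihood(500, lrf, 67, x, 3), 0)
  expect_equal(max(v) - min(v), 0, tolerance = 1e-9)
})

test_that("reconstruction is symmetric for mirror-symmetric charges", {
  tl <- get_tiling(1)
  lrf <- synthetic_lrf(tl)
  # event on an interior pixel centre; M_rec = 25 makes the used
  # neighbourhood (pixel + ring of 8 + ring of 16) mirror-symmetric
  g <- tl$groups
  seed <- which.min((g$cx - 3.125)^2 + (g$cy - 3.125)^2)
  x0 <- g$cx[seed]; y0 <- g$cy[seed]
  used <- nearest_groups(tl, seed, 25)
  q <- rep(0, tl$n_groups)
  q[used] <- round(2000 * evaluate_lrf_set(lrf, used, x0, y0))
  # force exact mirror symmetry about the pixel centre
  for (gg in used) {
    gm <- which(abs(g$cx - (2 * x0 - g$cx[gg])) < 1e-9 &
                  abs(g$cy - g$cy[gg]) < 1e-9)
    q[gm] <- q[gg]
  }
  rc <- reconstruct_events(q, tl, lrf, recon_config(M_rec = 25))
  expect_lt(abs(rc$x - x0), 0.02)
})

test_that("optimizer matches the 0.1 mm grid-search oracle", {
  pl <- get_pipeline(1, "room")
  set.seed(50)
  ds <- lasipcam:::simulate_group_dataset(
    pl$cfg, pl$tiling, source_spec("flatfield", limits = c(40, 40)), 6,
    pl$noise)
  rc <- reconstruct_events(ds$charges, pl$tiling, pl$lrf, pl$recon)
  for (i in seq_len(nrow(ds$charges))) {
    gs <- lasipcam:::grid_search_position(ds$charges[i, ], pl$tiling, pl$lrf,
                                          pl$recon, step = 0.1)
    expect_lt(abs(rc$x[i] - gs$x), 0.1 + 1e-9)
    expect_lt(abs(rc$y[i] - gs$y), 0.1 + 1e-9)
    expect_lte(rc$nll[i], gs$nll + 1e-6)
  }
})

test_that("shifting charges by one pixel pitch shifts the position by one pitch", {
  tl <- get_tiling(1)
  lrf <- synthetic_lrf(tl)
  set.seed(51)
  counts <- sample_events(std_optics(), tl$layout, c(-5, 3))
  q <- drop(group_charges(counts, tl))
  rc1 <- reconstruct_events(q, tl, lrf)
  # shift the whole charge pattern one pixel column to the right
  g <- tl$groups
  q2 <- rep(0, tl$n_groups)
  for (i in seq_len(tl$n_groups)) {
    tgt <- which(abs(g$cx - g$cx[i] - 18.75) < 1e-9 &
                   abs(g$cy - g$cy[i]) < 1e-9)
    if (length(tgt)) q2[tgt] <- q[i]
  }
  rc2 <- reconstruct_events(q2, tl, lrf)
  expect_equal(rc2$x - rc1$x, 18.75, tolerance = 0.05)
  expect_equal(rc2$y, rc1$y, tolerance = 0.05)
})

test_that("returned optimum never exceeds the seed NLL and stays inside r_rec", {
  pl <- get_pipeline(1, "room")
  set.seed(52)
  ds <- lasipcam:::simulate_group_dataset(
    pl$cfg, pl$tiling, source_spec("flatfield", limits = c(50, 50)), 40,
    pl$noise)
  rc <- reconstruct_events(ds$charges, pl$tiling, pl$lrf, pl$recon)
  g <- pl$tiling$groups
  ok <- pl$lrf$ok
  nb <- lasipcam:::.neighbor_matrix_ok(pl$tiling, pl$recon$M_rec, ok)
  for (i in seq_len(nrow(ds$charges))) {
    s <- rc$seed[i]
    used <- nb[s, ]
    seed_nll <- neg_log_likelihood(ds$charges[i, used], pl$lrf, used,
                                   g$cx[s], g$cy[s])
    expect_lte(rc$nll[i], seed_nll + 1e-6)
    expect_lte(sqrt((rc$x[i] - g$cx[s])^2 + (rc$y[i] - g$cy[s])^2),
               pl$recon$r_rec + 1e-6)
  }
})

test_that("noiseless point-source reconstruction is unbiased below 0.2 mm", {
  pl <- get_pipeline(1, "room")
  set.seed(53)
  ds <- lasipcam:::simulate_group_dataset(
    pl$cfg, pl$tiling, source_spec("point", x = 0, y = 0), 200)
  rc <- reconstruct_events(ds$charges, pl$tiling, pl$lrf, pl$recon)
  expect_lt(abs(mean(rc$x)), 0.2)
  expect_lt(abs(mean(rc$y)), 0.2)
  expect_equal(mean(rc$converged), 1)
})

test_that("using more than 21 pixels does not significantly change the resolution", {
  pl <- get_pipeline(1, "room")
  set.seed(54)
  ds <- lasipcam:::simulate_group_dataset(
    pl$cfg, pl$tiling, source_spec("point", x = -5, y = 3), 400, pl$noise)
  rc21 <- reconstruct_events(ds$charges, pl$tiling, pl$lrf, recon_config(21))
  rc30 <- reconstruct_events(ds$charges, pl$tiling, pl$lrf, recon_config(30))
  # paired events: the point-spread width changes by at most 5%
  s21 <- sd(rc21$x)
  s30 <- sd(rc30$x)
  expect_lt(abs(s30 - s21) / s21, 0.05)
})
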