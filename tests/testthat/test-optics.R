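# Synthetic scintillation-light generator.

test_that("photon budget follows the configured chain of efficiencies", {
  cfg <- optics_config()
  # 140 keV * 38 ph/keV * 0.6 * 0.5 * (1 - exp(-600/230))
  expect_equal(expected_photons(cfg),
               140 * 38 * 0.6 * 0.5 * (1 - exp(-600 / 230)), tolerance = 1e-12)
  expect_equal(expected_photons(cfg), 1478.486, tolerance = 1e-4)
  expect_equal(acceptance_fraction(cfg), 0.9263695, tolerance = 1e-6)
  expect_gte(acceptance_fraction(cfg), 0.90)
})

test_that("limiting case recovers the raw Poisson photon count", {
  cfg <- optics_config(pde = 1, collection_eff = 1, integration_time = 1e9,
                       intrinsic_sigma = 0)
  expect_equal(expected_photons(cfg), 5320, tolerance = 1e-6)
  lay <- get_layout("square")
  set.seed(42)
  counts <- sample_events(cfg, lay, matrix(rep(c(0, 0), 50), ncol = 2,
                                           byrow = TRUE))
  tot <- rowSums(counts)
  # mean within 5 sigma of 5320, variance compatible with Poisson
  expect_lt(abs(mean(tot) - 5320), 5 * sqrt(5320 / 50))
  expect_gt(var(tot), 5320 * 0.5)
  expect_lt(var(tot), 5320 * 2)
})

test_that("sampling is deterministic under a fixed seed", {
  cfg <- std_optics()
  lay <- get_layout("square")
  set.seed(7); a <- sample_event(cfg, lay, 3, -5)
  set.seed(7); b <- sample_event(cfg, lay, 3, -5)
  expect_identical(a, b)
})

test_that("positions outside the instrumented region are rejected", {
  lay <- get_layout("square")
  expect_error(sample_event(std_optics(), lay, 150, 0), "outside")
  expect_error(sample_positions(source_spec("point", x = 0, y = 200), 5, lay),
               "outside")
})

test_that("kernel integral matches a numerical integration of the spread function", {
  lay <- get_layout("square")
  cfg <- optics_config(diffuse_fraction = 0)
  src <- c(2.0, -4.5)
  p <- integrate_kernel(cfg, lay, src[1], src[2])
  # independent oracle: Riemann sum of K(r; h) = h / (4 pi (r^2+h^2)^(3/2))
  # (solid-angle fraction of an isotropic emitter) over single cells
  h <- cfg$h_eff
  riemann <- function(cell) {
    step <- 0.02
    gx <- seq(cell$x - 3 + step / 2, cell$x + 3 - step / 2, by = step) - src[1]
    gy <- seq(cell$y - 3 + step / 2, cell$y + 3 - step / 2, by = step) - src[2]
    rr2 <- outer(gx^2, gy^2, `+`)
    sum(h / (4 * pi * (rr2 + h^2)^1.5)) * step^2
  }
  cells <- lay$cells
  near <- which.min((cells$x - src[1])^2 + (cells$y - src[2])^2)
  far <- which.min((cells$x - src[1] - 40)^2 + (cells$y - src[2])^2)
  expect_equal(p[near], riemann(cells[near, ]), tolerance = 1e-3)
  expect_equal(p[far], riemann(cells[far, ]), tolerance = 1e-3)
  # over a wide plane the kernel sums to at most the lower half sphere
  wide <- build_grid("square", c(600, 600), 6, 0.25)
  pw <- integrate_kernel(cfg, wide, 2.0, -4.5)
  expect_lt(sum(pw), 0.5)
  expect_gt(sum(pw), 0.40)
})

test_that("kernel probability is symmetric and decreases with distance", {
  lay <- get_layout("square")
  cfg <- optics_config(diffuse_fraction = 0)
  cells <- lay$cells
  # source on the centre of an interior cell
  ic <- which.min((cells$x - 3.125)^2 + (cells$y - 3.125)^2)
  x0 <- cells$x[ic]; y0 <- cells$y[ic]
  p <- integrate_kernel(cfg, lay, x0, y0)
  left <- which(cells$y == y0 & cells$x == x0 - 6.25)
  right <- which(cells$y == y0 & cells$x == x0 + 6.25)
  expect_equal(p[left], p[right], tolerance = 1e-10)
  # strictly decreasing along the row
  row <- cells$y == y0 & cells$x >= x0
  ord <- order(cells$x[row])
  expect_true(all(diff(p[row][ord]) < 0))
  # near-source limit: the cell under the source captures ~ half the sphere
  cfg0 <- optics_config(h_eff = 1e-3, diffuse_fraction = 0)
  p0 <- integrate_kernel(cfg0, lay, x0, y0, cell_ids = ic)
  expect_equal(p0, 0.5, tolerance = 1e-3)
})

test_that("source geometries generate the advertised position distributions", {
  lay <- get_layout("square")
  set.seed(11)
  pp <- sample_positions(source_spec("point", x = 0, y = 0), 5, lay)
  expect_true(all(pp == 0))
  cp <- sample_positions(source_spec("capillary", x = 10), 200, lay)
  expect_true(all(cp[, 1] == 10))
  expect_gt(diff(range(cp[, 2])), 50)
  ff <- sample_positions(source_spec("flatfield"), 1000, lay)
  ks <- suppressWarnings(stats::ks.test(ff[, 1], "punif", -112.5, 112.5))
  expect_gt(ks$p.value, 0.01)
  dz <- sample_positions(source_spec("derenzo"), 500, lay)
  circ <- derenzo_circles(source_spec("derenzo"))
  dmin <- apply(dz, 1, function(p)
    min(sqrt((circ$x - p[1])^2 + (circ$y - p[2])^2) - circ$d / 2))
  expect_true(all(dmin <= 1e-9))
})

test_that("derenzo pattern has all six diameter classes with non-overlapping circles", {
  circ <- derenzo_circles(source_spec("derenzo"))
  expect_setequal(unique(circ$d), c(1, 2, 3, 4, 6, 8))
  d <- as.matrix(dist(cbind(circ$x, circ$y)))
  diag(d) <- Inf
  rsum <- outer(circ$d / 2, circ$d / 2, `+`)
  expect_true(all(d > rsum - 1e-9))
})

test_that("detected photons are conserved through the multinomial split", {
  cfg <- std_optics()
  lay <- get_layout("square")
  set.seed(3)
  counts <- sample_events(cfg, lay, matrix(rep(c(5, -10), 100), ncol = 2,
                                           byrow = TRUE))
  tot <- rowSums(counts)
  expect_true(all(counts >= 0))
  # totals compatible with the configured expectation
  expect_lt(abs(mean(tot) - expected_photons(cfg)),
            5 * sd(tot) / sqrt(length(tot)))
})
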