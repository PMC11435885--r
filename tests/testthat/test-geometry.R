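# SiPM grid construction and LASiP groupings.

# Independent occupancy oracle: count cells row by row from the packing
# arithmetic, scanning candidate positions rather than using the layout
# formula.
count_cells_scan <- function(kind, W, H, side, gap) {
  pitch <- side + gap
  n <- 0L
  j <- 0L
  repeat {
    y0 <- j * pitch + gap / 2
    if (y0 + side > H) break
    off <- if (kind == "honeycomb" && j %% 2L == 1L) pitch / 2 else 0
    x0 <- off + gap / 2
    while (x0 + side <= W + 1e-9) {
      n <- n + 1L
      x0 <- x0 + pitch
    }
    j <- j + 1L
  }
  n
}

test_that("square grid of the 225 mm region holds exactly 1296 SiPMs", {
  lay <- get_layout("square")
  expect_equal(lay$n_cells, 1296L)
  expect_equal(lay$n_cells, count_cells_scan("square", 225, 225, 6, 0.25))
  # pitch between adjacent cells in a row
  r0 <- lay$cells[lay$cells$row == 0, ]
  expect_equal(unique(round(diff(r0$x), 9)), 6.25)
  # all cells inside the region
  expect_true(all(abs(lay$cells$x) <= 112.5 - 3) &&
                all(abs(lay$cells$y) <= 112.5 - 3))
})

test_that("honeycomb grid count matches a brute-force occupancy scan", {
  lay <- get_layout("honeycomb")
  n_scan <- count_cells_scan("honeycomb", 225, 225, 6, 0.25)
  expect_equal(lay$n_cells, n_scan)
  expect_true(lay$n_cells >= 1260 && lay$n_cells <= 1296)
  # odd rows offset by half a pitch
  x_even <- min(lay$cells$x[lay$cells$row == 0])
  x_odd <- min(lay$cells$x[lay$cells$row == 1])
  expect_equal(x_odd - x_even, 6.25 / 2)
})

test_that("degenerate regions build one cell or fail", {
  one <- build_grid("square", c(6.25, 6.25), 6, 0.25)
  expect_equal(one$n_cells, 1L)
  expect_error(build_grid("square", c(5, 5), 6, 0.25), "smaller")
})

test_that("all eight groupings reproduce the configured size/area pairs and partition the cells", {
  for (m in 1:8) {
    tl <- get_tiling(m)
    full <- !tl$groups$partial
    expect_true(any(full), info = paste("model", m))
    expect_equal(unique(tl$groups$n_members[full]), lasip_models$n_sipm[m],
                 info = paste("model", m))
    expect_equal(unique(tl$groups$area[full]), lasip_models$area[m],
                 info = paste("model", m))
    # partition: every cell in exactly one group
    expect_equal(sum(tl$groups$n_members), tl$layout$n_cells,
                 info = paste("model", m))
    expect_true(all(tl$cell_gid %in% tl$groups$gid))
    # group members are contiguous (each cell adjacent to another member)
    cells <- tl$layout$cells
    for (g in sample(tl$groups$gid[full], 5)) {
      idx <- tl$members[[g]]
      if (length(idx) == 1) next
      d <- as.matrix(dist(cells[idx, c("x", "y")]))
      diag(d) <- Inf
      expect_true(all(apply(d, 1, min) < 1.5 * tl$layout$pitch),
                  info = paste("model", m, "group", g))
    }
  }
})

test_that("model 1 yields 144 groups of 9 and a whole 6x6 grid is one pixel", {
  expect_equal(get_tiling(1)$n_groups, 144L)
  small <- build_grid("square", c(37.5, 37.5), 6, 0.25)
  expect_equal(small$n_cells, 36L)
  tl <- group_pixels(small, 4)
  expect_equal(tl$n_groups, 1L)
  expect_equal(tl$groups$n_members, 36L)
})

test_that("incompatible layout/model combinations are rejected", {
  expect_error(group_pixels(get_layout("square"), 6), "honeycomb")
  expect_error(group_pixels(get_layout("honeycomb"), 5), "square")
  expect_error(group_pixels(get_layout("square"), 9), "1..8")
})

test_that("nearest_groups matches a brute-force distance sort", {
  tl <- get_tiling(1)
  g <- tl$groups
  seed <- g$gid[which.min((g$cx - 3)^2 + (g$cy - 3)^2)]  # interior
  expect_equal(nearest_groups(tl, seed, 1), seed)
  got <- nearest_groups(tl, seed, 9)
  d <- sqrt((g$cx - g$cx[seed])^2 + (g$cy - g$cy[seed])^2)
  expect_setequal(got, g$gid[order(d, g$gid)][1:9])
  expect_equal(got[1], seed)
  # the 8 surrounding pixels of an interior square pixel
  expect_true(all(abs(g$cx[got[-1]] - g$cx[seed]) <= 18.75 + 1e-9))

  tlh <- get_tiling(6)
  gh <- tlh$groups
  seedh <- gh$gid[!gh$partial][which.min(
    gh$cx[!gh$partial]^2 + gh$cy[!gh$partial]^2)]
  goth <- nearest_groups(tlh, seedh, 7)
  dh <- sqrt((gh$cx - gh$cx[seedh])^2 + (gh$cy - gh$cy[seedh])^2)
  expect_setequal(goth, gh$gid[order(dh, gh$gid)][1:7])
  # a comb pixel has a ring of 6 comparable-distance neighbours
  ring <- dh[order(dh)][2:7]
  expect_lt(max(ring) / min(ring), 1.25)
})

test_that("tilings round-trip through the text serialisation", {
  tl <- get_tiling(6)
  path <- tempfile(fileext = ".tsv")
  write_tiling(tl, path)
  tl2 <- read_tiling(path)
  expect_equal(tl2$cell_gid, tl$cell_gid)
  expect_equal(tl2$groups$cx, tl$groups$cx)
})
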