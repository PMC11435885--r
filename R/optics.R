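# Parametric scintillation-light generator.
#
# Stands in for a full optical Monte Carlo: a 140 keV deposition at (x, y)
# produces a Poisson number of detected photoelectrons whose expectation is
# energy * light_yield * collection_eff * pde * (1 - exp(-T_int / tau)),
# multiplied by a truncated-Gaussian intrinsic-resolution factor, and the
# photons are split over the SiPM cells by a multinomial draw.  The
# per-cell weights combine the solid angle each cell subtends from an
# effective emission point at height h_eff above the detector plane with a
# uniform diffuse term standing in for reflector light.

#' Optics configuration
#'
#' @param energy deposited energy in keV.
#' @param light_yield scintillation yield in photons/keV.
#' @param pde SiPM photodetection efficiency (fraction).
#' @param collection_eff effective light-collection efficiency folded over
#'   geometry and reflector transport (fraction).
#' @param decay_time scintillation decay constant in ns.
#' @param integration_time charge-integration window in ns.
#' @param crystal_thickness,glass_thickness mm; their combination sets the
#'   default effective emission height `h_eff = crystal/2 + glass`.
#' @param h_eff effective height of the emission point above the SiPM
#'   plane, mm.
#' @param diffuse_fraction fraction of detected light spread uniformly over
#'   the instrumented area (reflector light).
#' @param intrinsic_sigma relative width of the multiplicative Gaussian
#'   smearing of the total photon count (scintillator intrinsic
#'   resolution); calibrate with [calibrate_intrinsic()].
#' @return list of class `optics_config`.
#' @export
optics_config <- function(energy = 140, light_yield = 38, pde = 0.50,
                          collection_eff = 0.6, decay_time = 230,
                          integration_time = 600, crystal_thickness = 9,
                          glass_thickness = 1,
                          h_eff = crystal_thickness / 2 + glass_thickness,
                          diffuse_fraction = 0.15, intrinsic_sigma = 0) {
  stopifnot(energy > 0, light_yield > 0,
            pde > 0, pde <= 1, collection_eff > 0, collection_eff <= 1,
            decay_time > 0, integration_time > 0, h_eff > 0,
            diffuse_fraction >= 0, diffuse_fraction <= 1,
            intrinsic_sigma >= 0)
  structure(list(energy = energy, light_yield = light_yield, pde = pde,
                 collection_eff = collection_eff, decay_time = decay_time,
                 integration_time = integration_time,
                 crystal_thickness = crystal_thickness,
                 glass_thickness = glass_thickness, h_eff = h_eff,
                 diffuse_fraction = diffuse_fraction,
                 intrinsic_sigma = intrinsic_sigma),
            class = "optics_config")
}

#' Fraction of scintillation photons inside the integration window
#' @param cfg an `optics_config`.
#' @export
acceptance_fraction <- function(cfg) {
  1 - exp(-cfg$integration_time / cfg$decay_time)
}

#' Expected number of detected photoelectrons per event
#' @param cfg an `optics_config`.
#' @export
expected_photons <- function(cfg) {
  cfg$energy * cfg$light_yield * cfg$collection_eff * cfg$pde *
    acceptance_fraction(cfg)
}

# Solid angle (sr) subtended by the rectangle [x1,x2] x [y1,y2] in the
# plane z = 0 from a point at (0, 0, h), by signed corner decomposition.
.omega_rect <- function(x1, x2, y1, y2, h) {
  f <- function(a, b) atan2(a * b, h * sqrt(a * a + b * b + h * h))
  f(x2, y2) - f(x1, y2) - f(x2, y1) + f(x1, y1)
}

#' Probability that a detected photon lands on a given cell
#'
#' Combines the solid-angle fraction of an isotropic emitter at height
#' `h_eff` (a cell directly under the source captures up to half the
#' emission sphere as `h_eff` tends to 0) with a uniform diffuse term.
#'
#' @param cfg an `optics_config`.
#' @param layout a `camera_layout`.
#' @param x,y source position, mm.
#' @param cell_ids cells to evaluate (default all).
#' @return numeric vector of per-cell probabilities; their sum over all
#'   cells plus the loss term is at most 1.
#' @export
integrate_kernel <- function(cfg, layout, x, y, cell_ids = NULL) {
  cells <- layout$cells
  if (!is.null(cell_ids)) cells <- cells[cell_ids, , drop = FALSE]
  half <- layout$side / 2
  om <- .omega_rect(cells$x - half - x, cells$x + half - x,
                    cells$y - half - y, cells$y + half - y, cfg$h_eff)
  (1 - cfg$diffuse_fraction) * om / (4 * pi) +
    cfg$diffuse_fraction * layout$cell_area /
      (layout$region[1] * layout$region[2])
}

# Multinomial sampling weights over the instrumented cells for each source
# position: solid-angle weights renormalised over the cells (collection_eff
# absorbs the overall geometric loss) mixed with the diffuse term.
# pos: n x 2 matrix.  Returns n x n_cells matrix of probabilities (rows sum
# to 1).
.cell_prob_matrix <- function(cfg, layout, pos) {
  cells <- layout$cells
  half <- layout$side / 2
  h <- cfg$h_eff
  f <- function(a, b) atan2(a * b, h * sqrt(a * a + b * b + h * h))
  x1 <- outer(-pos[, 1], cells$x - half, `+`)
  x2 <- x1 + layout$side
  y1 <- outer(-pos[, 2], cells$y - half, `+`)
  y2 <- y1 + layout$side
  om <- f(x2, y2) - f(x1, y2) - f(x2, y1) + f(x1, y1)
  om <- om / rowSums(om)
  cfg$diffuse_fraction / ncol(om) + (1 - cfg$diffuse_fraction) * om
}

.inside_region <- function(layout, pos) {
  all(abs(pos[, 1]) <= layout$region[1] / 2 + 1e-9) &&
    all(abs(pos[, 2]) <= layout$region[2] / 2 + 1e-9)
}

#' Sample per-SiPM photon counts for scintillation events
#'
#' @param cfg an `optics_config`.
#' @param layout a `camera_layout`.
#' @param pos n x 2 matrix (or length-2 vector) of true positions in mm.
#' @return integer matrix, events x cells, of detected photon counts.
#' @export
sample_events <- function(cfg, layout, pos) {
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 2)
  if (!.inside_region(layout, pos)) stop("source position outside region")
  n <- nrow(pos)
  nbar <- expected_photons(cfg)
  tot <- stats::rpois(n, nbar)
  if (cfg$intrinsic_sigma > 0)
    tot <- round(tot * pmax(0, 1 + stats::rnorm(n, 0, cfg$intrinsic_sigma)))
  counts <- matrix(0L, n, layout$n_cells)
  chunk <- 1000L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    p <- .cell_prob_matrix(cfg, layout, pos[s:e, , drop = FALSE])
    for (i in s:e)
      counts[i, ] <- stats::rmultinom(1, tot[i], p[i - s + 1L, ])
  }
  counts
}

#' @rdname sample_events
#' @param x,y single true position in mm.
#' @export
sample_event <- function(cfg, layout, x, y) {
  drop(sample_events(cfg, layout, c(x, y)))
}

#' Source specification
#'
#' @param kind `"point"`, `"capillary"`, `"flatfield"` or `"derenzo"`.
#' @param x,y point position (point) or line offset (capillary), mm.
#' @param angle capillary orientation in degrees, 0 = vertical.
#' @param length capillary length, mm.
#' @param limits flat-field half-extents `c(hx, hy)`, mm; default the full
#'   instrumented region.
#' @param diameters,disc_radius Derenzo circle diameters (with neighbour
#'   spacing 2d) and pattern radius, mm.
#' @export
source_spec <- function(kind = c("point", "capillary", "flatfield", "derenzo"),
                        x = 0, y = 0, angle = 0, length = 120,
                        limits = NULL,
                        diameters = c(1, 2, 3, 4, 6, 8), disc_radius = 45) {
  kind <- match.arg(kind)
  structure(list(kind = kind, x = x, y = y, angle = angle, length = length,
                 limits = limits, diameters = diameters,
                 disc_radius = disc_radius),
            class = "source_spec")
}

# Circle centres of the simile-Derenzo pattern: six 60-degree sectors, one
# per diameter, each filled with a triangular lattice of centre spacing 2d
# clipped to the sector with an inner clearance.
#' @rdname source_spec
#' @param spec a `source_spec` of kind `"derenzo"`.
#' @export
derenzo_circles <- function(spec) {
  out <- list()
  for (k in seq_along(spec$diameters)) {
    d <- spec$diameters[k]
    s <- 2 * d
    # triangular lattice, rows along the sector bisector
    i <- seq(-40, 40)
    g <- expand.grid(i = i, j = i)
    px <- g$i * s + (g$j %% 2) * s / 2
    py <- g$j * s * sqrt(3) / 2
    r <- sqrt(px^2 + py^2)
    th <- atan2(py, px)
    a0 <- (k - 1) * pi / 3 + pi / 12   # rotate pattern into sector k
    keep <- r >= max(6, 2 * d) & r <= spec$disc_radius - d / 2
    thk <- (th - a0) %% (2 * pi)
    keep <- keep & (thk <= pi / 3 - d / r | thk >= 2 * pi - 1e-9)
    if (any(keep))
      out[[k]] <- data.frame(x = px[keep], y = py[keep], d = d)
  }
  do.call(rbind, out)
}

#' Sample true event positions from a source
#'
#' @param spec a `source_spec`.
#' @param n number of events.
#' @param layout a `camera_layout` (used for flat-field extents and bounds
#'   checking).
#' @return n x 2 matrix of positions.
#' @export
sample_positions <- function(spec, n, layout) {
  stopifnot(n > 0)
  pos <- switch(spec$kind,
    point = cbind(rep(spec$x, n), rep(spec$y, n)),
    capillary = {
      t <- stats::runif(n, -spec$length / 2, spec$length / 2)
      a <- spec$angle * pi / 180
      cbind(spec$x - t * sin(a), spec$y + t * cos(a))
    },
    flatfield = {
      lim <- if (is.null(spec$limits)) layout$region / 2 else spec$limits
      cbind(stats::runif(n, -lim[1], lim[1]), stats::runif(n, -lim[2], lim[2]))
    },
    derenzo = {
      circ <- derenzo_circles(spec)
      idx <- sample.int(nrow(circ), n, replace = TRUE, prob = circ$d^2)
      r <- circ$d[idx] / 2 * sqrt(stats::runif(n))
      a <- stats::runif(n, 0, 2 * pi)
      cbind(circ$x[idx] + r * cos(a), circ$y[idx] + r * sin(a))
    })
  if (!.inside_region(layout, pos)) stop("source position outside region")
  pos
}

#' Generate a dataset of events with per-pixel charges
#'
#' Simulates `n` scintillation events, optionally injects SiPM noise, and
#' sums the per-SiPM counts into per-LASiP charges.
#'
#' @param cfg an `optics_config`.
#' @param tiling a `lasip_tiling`.
#' @param spec a `source_spec`.
#' @param n number of events.
#' @param noise a `noise_config`, or `NULL` for a noiseless dataset.
#' @return list with `true` (n x 2 positions) and `charges` (n x n_groups).
#' @export
generate_dataset <- function(cfg, tiling, spec, n, noise = NULL) {
  layout <- tiling$layout
  pos <- sample_positions(spec, n, layout)
  charges <- matrix(0, n, tiling$n_groups)
  chunk <- 2000L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    counts <- sample_events(cfg, layout, pos[s:e, , drop = FALSE])
    charges[s:e, ] <- if (is.null(noise)) group_charges(counts, tiling)
                      else add_noise(counts, tiling, noise)
  }
  list(true = pos, charges = charges)
}
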