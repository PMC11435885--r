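# SiPM noise injection: dark counts, Borel-branching optical crosstalk and
# an optional LASiP-size-dependent electronic term.
#
# Every primary avalanche (detected photon or dark count) triggers a
# Borel-distributed number of avalanches with branching parameter
# lambda = -log(1 - p_ct), so the probability that a primary produces at
# least one crosstalk avalanche is exactly p_ct and the mean multiplicity
# is 1 / (1 - lambda).

#' Noise configuration
#'
#' Presets follow the three studied dark-count levels: `"cooled"`
#' (0.015 MHz/mm2, SiPMs at ~4 C), `"room"` (0.050 MHz/mm2) and `"hot"`
#' (0.150 MHz/mm2); `"none"` keeps crosstalk active with zero DCR.
#'
#' @param preset one of `"none"`, `"cooled"`, `"room"`, `"hot"`, or `NULL`
#'   when passing `dcr` directly.
#' @param dcr dark count rate in MHz per mm2 of SiPM area.
#' @param crosstalk_prob optical crosstalk probability (fraction).
#' @param integration_time integration window in ns.
#' @param elec_sigma_coeff electronic noise in p.e. per sqrt(number of
#'   summed SiPMs); interpretation knob, default 0.
#' @return list of class `noise_config`.
#' @export
noise_config <- function(preset = NULL, dcr = NULL, crosstalk_prob = 0.25,
                         integration_time = 600, elec_sigma_coeff = 0) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("none", "cooled", "room", "hot"))
    dcr <- c(none = 0, cooled = 0.015, room = 0.050, hot = 0.150)[[preset]]
  }
  stopifnot(!is.null(dcr), dcr >= 0, crosstalk_prob >= 0, crosstalk_prob < 1,
            integration_time > 0, elec_sigma_coeff >= 0)
  structure(list(preset = if (is.null(preset)) "custom" else preset,
                 dcr = dcr, crosstalk_prob = crosstalk_prob,
                 integration_time = integration_time,
                 elec_sigma_coeff = elec_sigma_coeff,
                 lambda = -log(1 - crosstalk_prob)),
            class = "noise_config")
}

# Mean dark primaries per SiPM in one integration window.
.dark_mean <- function(noise, cell_area) {
  noise$dcr * cell_area * noise$integration_time * 1e-3
}

# Total avalanches of a Borel-branching cascade started by `n` primaries,
# vectorised over an integer vector.
rborel_total <- function(n, lambda) {
  tot <- n
  gen <- n
  if (lambda <= 0) return(tot)
  repeat {
    alive <- which(gen > 0L)
    if (!length(alive)) break
    nxt <- stats::rpois(length(alive), lambda * gen[alive])
    gen[] <- 0L
    gen[alive] <- nxt
    tot[alive] <- tot[alive] + nxt
  }
  tot
}

#' Inject SiPM noise and sum cells into LASiP charges
#'
#' Adds Poisson dark primaries per SiPM, multiplies every primary by a
#' Borel crosstalk cascade, sums the member SiPMs of each pixel and adds
#' the optional Gaussian electronic term; charges are floored at 0.
#'
#' @param counts integer matrix, events x cells, of detected photons.
#' @param tiling a `lasip_tiling`.
#' @param noise a `noise_config`.
#' @return numeric matrix, events x groups, of noisy charges in p.e.
#' @export
add_noise <- function(counts, tiling, noise) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  layout <- tiling$layout
  stopifnot(ncol(counts) == layout$n_cells)
  n <- nrow(counts)
  mu <- .dark_mean(noise, layout$cell_area)
  prim <- counts
  if (mu > 0)
    prim <- prim + stats::rpois(length(prim), mu)
  if (noise$lambda > 0) {
    dim_save <- dim(prim)
    prim <- rborel_total(as.integer(prim), noise$lambda)
    dim(prim) <- dim_save
  }
  q <- group_charges(prim, tiling)
  if (noise$elec_sigma_coeff > 0) {
    sd_g <- noise$elec_sigma_coeff * sqrt(tiling$groups$n_members)
    q <- q + matrix(stats::rnorm(n * tiling$n_groups, 0, rep(sd_g, each = n)),
                    n, tiling$n_groups)
  }
  pmax(q, 0)
}

#' Expected dark charge per pixel
#'
#' Mean dark-count charge collected by each LASiP in one integration
#' window, including the Borel crosstalk mean multiplication
#' 1 / (1 - lambda).  Used as the known baseline in the charge-truncation
#' analysis.
#'
#' @param tiling a `lasip_tiling`.
#' @param noise a `noise_config`.
#' @return numeric vector, one expected charge (p.e.) per group.
#' @export
expected_dark_charge <- function(tiling, noise) {
  mu <- .dark_mean(noise, tiling$layout$cell_area)
  tiling$groups$n_members * mu / (1 - noise$lambda)
}
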