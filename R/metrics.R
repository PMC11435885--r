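# Intrinsic spatial resolution from line-source images, and resolvability
# of the simile-Derenzo pattern.
#
# A vertical capillary reconstructed at x_cap is sliced into narrow y
# bands centred on pixel-centre y coordinates; the x projection of each
# band is interpolated with a cubic spline whose half-maximum crossings
# give the band FWHM.  The mean of the band FWHM distribution is the
# spatial resolution at x_cap, its SD the quoted error.  d-hat is the
# distance from the capillary to the nearest pixel centre normalised to
# half the pixel pitch (0 = through a centre, 1 = at the edge).

#' Spline FWHM of a binned profile
#'
#' Cubic-spline interpolation of the profile; the FWHM is the distance
#' between the two half-maximum crossings bracketing the peak.
#'
#' @param counts bin contents.
#' @param centers bin centres, mm.
#' @return FWHM in mm.
#' @export
spline_fwhm <- function(counts, centers) {
  keep <- is.finite(counts)
  counts <- counts[keep]; centers <- centers[keep]
  if (sum(counts > 0) < 5) stop("profile has fewer than 5 populated bins")
  sp <- stats::splinefun(centers, counts, method = "natural")
  xx <- seq(centers[1], centers[length(centers)], length.out = 2048)
  vv <- sp(xx)
  ipk <- which.max(vv)
  half <- vv[ipk] / 2
  below_l <- which(vv[seq_len(ipk)] < half)
  below_r <- which(vv[ipk:length(vv)] < half)
  if (!length(below_l) || !length(below_r))
    stop("no half-maximum crossings bracket the peak")
  il <- max(below_l)
  ir <- ipk + min(below_r) - 1L
  xl <- stats::uniroot(function(x) sp(x) - half, c(xx[il], xx[ipk]))$root
  xr <- stats::uniroot(function(x) sp(x) - half, c(xx[ipk], xx[ir]))$root
  xr - xl
}

#' Pixel pitch of a tiling
#'
#' Median nearest-neighbour centroid spacing of the interior (non-partial)
#' pixels; the normalisation scale for d-hat.
#' @param tiling a `lasip_tiling`.
#' @return pitch in mm.
#' @export
pixel_pitch <- function(tiling) {
  g <- tiling$groups[!tiling$groups$partial, ]
  if (nrow(g) < 2) stop("tiling has fewer than two interior pixels")
  d <- as.matrix(stats::dist(cbind(g$cx, g$cy)))
  diag(d) <- Inf
  stats::median(apply(d, 1, min))
}

# Interior pixels a vertical capillary at x_cap is associated with: those
# whose centre is laterally within half a pitch, within |cy| <= y_range.
capillary_bands <- function(tiling, x_cap, y_range = 40) {
  s <- pixel_pitch(tiling)
  g <- tiling$groups[!tiling$groups$partial, ]
  g <- g[abs(g$cy) <= y_range & abs(g$cx - x_cap) <= s / 2 + 1e-9, ]
  if (!nrow(g)) stop("no interior pixel bands for this capillary position")
  data.frame(gid = g$gid, y = g$cy,
             dhat = pmin(abs(g$cx - x_cap) / (s / 2), 1))
}

#' Spatial resolution of a reconstructed capillary
#'
#' @param pos corrected reconstructed positions (n x 2) of a vertical
#'   capillary dataset.
#' @param tiling the `lasip_tiling`.
#' @param x_cap true capillary x position, mm.
#' @param y_range half-extent of the analysed y range, mm.
#' @param band_halfwidth half-width of each y band, mm.
#' @param bin_width projection histogram bin width, mm.
#' @param x_halfspan half-extent of the projection around `x_cap`, mm.
#' @param umap optional `uniformity_map`; when given, projection bins are
#'   weighted by the map value at the bin position before the spline fit.
#' @param min_bands minimum number of valid bands required.
#' @return list: per-band table (`gid`, `y`, `dhat`, `fwhm`), `mean`, `sd`
#'   and the capillary `dhat`.
#' @export
capillary_resolution <- function(pos, tiling, x_cap, y_range = 40,
                                 band_halfwidth = 1.25, bin_width = 0.5,
                                 x_halfspan = 15, umap = NULL,
                                 min_bands = 3) {
  if (is.data.frame(pos)) pos <- cbind(pos$x, pos$y)
  bands <- capillary_bands(tiling, x_cap, y_range)
  fw <- rep(NA_real_, nrow(bands))
  for (b in seq_len(nrow(bands))) {
    sel <- is.finite(pos[, 1]) &
      abs(pos[, 2] - bands$y[b]) <= band_halfwidth &
      abs(pos[, 1] - x_cap) <= x_halfspan
    if (sum(sel) < 30) next
    # refine the binning until the profile is sampled by enough bins
    for (bw in bin_width / c(1, 2, 4)) {
      br <- seq(x_cap - x_halfspan, x_cap + x_halfspan, by = bw)
      mid <- (br[-1] + br[-length(br)]) / 2
      cnt <- graphics::hist(pos[sel & pos[, 1] >= br[1] &
                                  pos[, 1] < br[length(br)], 1],
                            breaks = br, plot = FALSE)$counts
      if (sum(cnt > 0) >= 5) break
    }
    if (!is.null(umap))
      cnt <- cnt * .interp_lattice(umap$xmid, umap$ymid, umap$map,
                                   mid, rep(bands$y[b], length(mid)))
    fw[b] <- tryCatch(spline_fwhm(cnt, mid), error = function(e) NA_real_)
  }
  bands$fwhm <- fw
  valid <- is.finite(fw)
  if (sum(valid) < min_bands)
    stop("fewer than ", min_bands, " valid projection bands")
  list(bands = bands, mean = mean(fw[valid]), sd = stats::sd(fw[valid]),
       n_bands = sum(valid), dhat = stats::median(bands$dhat))
}

#' FWHM versus normalised distance to the pixel centre
#'
#' Aggregates [capillary_resolution()] samples taken at several capillary
#' offsets into a d-hat curve.
#'
#' @param samples list of `capillary_resolution()` results.
#' @return data frame: `dhat`, `fwhm`, `sd`, `n_bands`.
#' @export
dhat_curve <- function(samples) {
  if (length(samples) < 2)
    stop("need capillary samples at two or more offsets")
  out <- do.call(rbind, lapply(samples, function(s)
    data.frame(dhat = s$dhat, fwhm = s$mean, sd = s$sd,
               n_bands = s$n_bands)))
  out[order(out$dhat), ]
}

#' Resolvability of the simile-Derenzo pattern
#'
#' A diameter class is resolved when the mean image intensity in the
#' valleys between adjacent circle centres falls below `frac` of the mean
#' intensity at the circle centres.
#'
#' @param image corrected `camera_image` of the Derenzo source.
#' @param circles the [derenzo_circles()] table.
#' @param frac valley-to-peak threshold.
#' @return data frame per diameter: `d`, `peak`, `valley`, `contrast`,
#'   `resolved`.
#' @export
derenzo_report <- function(image, circles, frac = 0.6) {
  lookup_mean <- function(x0, y0, rad) {
    rad <- max(rad, 0.75 * image$binwidth)   # never finer than the image
    kx <- which(abs(image$xmid - x0) <= rad)
    ky <- which(abs(image$ymid - y0) <= rad)
    if (!length(kx) || !length(ky)) return(NA_real_)
    sub <- image$counts[kx, ky, drop = FALSE]
    rr <- outer(image$xmid[kx] - x0, image$ymid[ky] - y0,
                function(a, b) sqrt(a^2 + b^2))
    mean(sub[rr <= rad])
  }
  out <- lapply(split(circles, circles$d), function(cc) {
    d <- cc$d[1]
    rad <- 0.35 * d
    peaks <- mapply(lookup_mean, cc$x, cc$y, MoreArgs = list(rad = rad))
    # valleys: midpoints of adjacent centre pairs (spacing 2d)
    dm <- as.matrix(stats::dist(cbind(cc$x, cc$y)))
    pairs <- which(dm > 1e-6 & dm < 2.2 * d, arr.ind = TRUE)
    pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
    if (!nrow(pairs))
      return(data.frame(d = d, peak = mean(peaks, na.rm = TRUE),
                        valley = NA_real_, contrast = NA_real_,
                        resolved = NA))
    vals <- apply(pairs, 1, function(p)
      lookup_mean((cc$x[p[1]] + cc$x[p[2]]) / 2,
                  (cc$y[p[1]] + cc$y[p[2]]) / 2, rad))
    pk <- mean(peaks, na.rm = TRUE)
    vl <- mean(vals, na.rm = TRUE)
    data.frame(d = d, peak = pk, valley = vl, contrast = vl / pk,
               resolved = is.finite(vl / pk) && vl / pk < frac)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
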