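# Light-response-function estimation.
#
# A gamma beam is simulated at each node of a square calibration grid; for
# every pixel the mean normalised charge q_ij / Q_j over the events of node
# j samples that pixel's LRF, which is then fitted with the radially
# symmetric generalised bell function
#   f(x, y) = a / (1 + (((x - d)^2 + (y - e)^2) / b^2)^c).

#' Calibration grid of point-source positions
#'
#' @param n_side nodes per side (default 21 x 21).
#' @param spacing lattice spacing in mm.
#' @param center grid centre, mm.
#' @return data frame with node index `j` and positions `x`, `y`.
#' @export
calibration_grid <- function(n_side = 21, spacing = 6.5, center = c(0, 0)) {
  u <- (seq_len(n_side) - (n_side + 1) / 2) * spacing
  g <- expand.grid(x = u + center[1], y = u + center[2])
  data.frame(j = seq_len(nrow(g)), x = g$x, y = g$y)
}

#' Collect LRF samples on a calibration grid
#'
#' Simulates `events_per_point` scintillation events at every grid node
#' (noiseless by default: the LRF is a detector property) and records the
#' per-pixel mean normalised charge and its standard error.  The
#' normalising charge Q_j is the full sum over all pixels.
#'
#' @param cfg an `optics_config`.
#' @param tiling a `lasip_tiling`.
#' @param grid a [calibration_grid()].
#' @param events_per_point events per node.
#' @param noise optional `noise_config` for noisy calibration.
#' @return list of class `lrf_samples`: `mean` and `se` (groups x nodes
#'   matrices) and the `grid`.
#' @export
collect_lrf_samples <- function(cfg, tiling, grid, events_per_point = 200,
                                noise = NULL) {
  stopifnot(events_per_point >= 2)
  G <- tiling$n_groups
  J <- nrow(grid)
  mn <- matrix(0, G, J)
  se <- matrix(0, G, J)
  for (j in seq_len(J)) {
    pos <- matrix(rep(c(grid$x[j], grid$y[j]), each = events_per_point),
                  ncol = 2)
    qg <- .sample_group_events(cfg, tiling, pos)
    if (!is.null(noise)) {
      qg <- .add_noise_groups(qg, tiling, noise)
      qg <- sweep(qg, 2L, expected_dark_charge(tiling, noise))
    }
    tot <- rowSums(qg)
    if (any(tot <= 0)) stop("empty events in calibration data")
    nq <- qg / tot
    mn[, j] <- colMeans(nq)
    se[, j] <- apply(nq, 2L, stats::sd) / sqrt(events_per_point)
  }
  structure(list(mean = mn, se = se, grid = grid), class = "lrf_samples")
}

.bell_formula <- m ~ a / (1 + (((x - d)^2 + (y - e)^2) / b^2)^c)

# Fit one pixel's samples; returns c(a, b, c, d, e, resid) or NULL.
.fit_bell_one <- function(x, y, m, w, start, pitch) {
  d <- data.frame(x = x, y = y, m = m, w = w)
  lower <- c(a = 1e-6, b = pitch / 10, c = 0.2, d = min(x) - pitch,
             e = min(y) - pitch)
  upper <- c(a = 1.5, b = 40 * pitch, c = 8,
             d = max(x) + pitch, e = max(y) + pitch)
  tries <- list(start,
                within(start, {b <- b * 2}),
                within(start, {c <- 2}),
                within(start, {b <- b / 2; c <- 0.7}),
                within(start, {d <- d + pitch / 3; e <- e - pitch / 3}))
  for (st in tries) {
    st <- as.list(pmin(pmax(unlist(st), lower + 1e-9), upper - 1e-9))
    fit <- try(minpack.lm::nlsLM(.bell_formula, data = d, start = st,
                                 weights = w, lower = lower, upper = upper,
                                 control = minpack.lm::nls.lm.control(
                                   maxiter = 200)), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      cf <- stats::coef(fit)
      rss <- sqrt(mean(stats::resid(fit)^2))
      return(c(cf[["a"]], cf[["b"]], cf[["c"]], cf[["d"]], cf[["e"]], rss))
    }
  }
  NULL
}

#' Fit bell-shaped LRFs to calibration samples
#'
#' Least-squares fit (weighted by the sample standard errors) of the
#' generalised bell function per pixel.  Nodes with mean normalised charge
#' below `floor` are excluded; pixels with fewer than `min_points` usable
#' nodes are flagged unusable.
#'
#' @param samples an `lrf_samples`.
#' @param tiling the matching `lasip_tiling`.
#' @param floor signal floor on the mean normalised charge.
#' @param min_points minimum usable calibration nodes per pixel.
#' @param coverage_margin pixels whose centroid lies further than this
#'   margin outside the calibration-grid span are flagged unusable: their
#'   peak is never sampled, so the fit is an unconstrained extrapolation.
#' @return list of class `lrf_model`: `params` (groups x 5 matrix with
#'   columns a, b, c, d, e), `resid`, `ok`.
#' @export
fit_bell <- function(samples, tiling, floor = 1e-3, min_points = 9,
                     coverage_margin = NULL) {
  G <- tiling$n_groups
  params <- matrix(NA_real_, G, 5,
                   dimnames = list(NULL, c("a", "b", "c", "d", "e")))
  resid <- rep(NA_real_, G)
  ok <- logical(G)
  pitch <- sqrt(tiling$n_sipm) * tiling$layout$pitch
  gx <- samples$grid$x; gy <- samples$grid$y
  for (g in seq_len(G)) {
    m <- samples$mean[g, ]
    keep <- m >= floor
    if (sum(keep) < min_points) next
    se <- pmax(samples$se[g, keep], 1e-6)
    start <- list(a = max(m), b = pitch, c = 1,
                  d = tiling$groups$cx[g], e = tiling$groups$cy[g])
    fit <- .fit_bell_one(gx[keep], gy[keep], m[keep], 1 / se^2, start, pitch)
    if (is.null(fit)) next
    params[g, ] <- fit[1:5]
    resid[g] <- fit[6]
    ok[g] <- TRUE
  }
  if (is.null(coverage_margin))
    coverage_margin <- tryCatch(pixel_pitch(tiling) / 2, error = function(e) {
      ux <- sort(unique(gx))
      if (length(ux) > 1) ux[2] - ux[1] else 10
    })
  covered <- tiling$groups$cx >= min(gx) - abs(coverage_margin) &
    tiling$groups$cx <= max(gx) + abs(coverage_margin) &
    tiling$groups$cy >= min(gy) - abs(coverage_margin) &
    tiling$groups$cy <= max(gy) + abs(coverage_margin)
  ok <- ok & covered
  structure(list(params = params, resid = resid, ok = ok,
                 model = tiling$model), class = "lrf_model")
}

#' Evaluate a fitted LRF
#'
#' @param lrf an `lrf_model`.
#' @param gid pixel (group) id.
#' @param x,y positions, mm (vectorised).
#' @return expected normalised charge of pixel `gid` at `(x, y)`.
#' @export
evaluate_lrf <- function(lrf, gid, x, y) {
  p <- lrf$params[gid, ]
  if (anyNA(p)) stop("no usable LRF fit for this pixel")
  .cpp_bell_eval(as.numeric(p), as.numeric(x), as.numeric(y))
}

#' Write / read an LRF model as a delimited table
#'
#' @param lrf an `lrf_model`.
#' @param path file path.
#' @export
write_lrf <- function(lrf, path) {
  df <- data.frame(gid = seq_len(nrow(lrf$params)), lrf$params,
                   resid = lrf$resid, ok = lrf$ok)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_lrf
#' @export
read_lrf <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  params <- as.matrix(df[, c("a", "b", "c", "d", "e")])
  dimnames(params) <- list(NULL, c("a", "b", "c", "d", "e"))
  structure(list(params = params, resid = df$resid, ok = df$ok,
                 model = NA_integer_), class = "lrf_model")
}
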