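# Event positioning by Poisson maximum likelihood over the fitted LRFs.

#' Reconstruction configuration
#'
#' @param M_rec number of pixels used per event: the maximum-charge pixel
#'   and its `M_rec - 1` nearest neighbours.
#' @param r_rec constraint radius around the seed-pixel centre, mm.
#' @param tol optimiser convergence tolerance (simplex size), mm.
#' @param maxit maximum optimiser iterations.
#' @export
recon_config <- function(M_rec = 21, r_rec = 40, tol = 1e-3, maxit = 300) {
  stopifnot(M_rec >= 1, r_rec > 0, tol > 0, maxit > 10)
  structure(list(M_rec = M_rec, r_rec = r_rec, tol = tol, maxit = maxit),
            class = "recon_config")
}

#' Negative Poisson log-likelihood of an event position
#'
#' Returns `sum_i [lam_i - q_i log lam_i]` with
#' `lam_i = f_i(x, y) * sum(q) / sum(f)` over the used pixels; equal to the
#' negative log likelihood up to charge-only constants.
#'
#' @param q charges of the used pixels.
#' @param lrf an `lrf_model`.
#' @param used_gids ids of the used pixels (same order as `q`).
#' @param x,y trial position, mm.
#' @export
neg_log_likelihood <- function(q, lrf, used_gids, x, y) {
  stopifnot(length(q) == length(used_gids))
  .cpp_nll(as.numeric(q), lrf$params, as.integer(used_gids), x, y)
}

#' Reconstruct event positions
#'
#' For each event the pixel with the maximum charge seeds a bounded 2-D
#' Nelder-Mead minimisation of the Poisson negative log likelihood over the
#' seed pixel and its nearest neighbours, constrained to a disc of radius
#' `r_rec`.  Non-converged events fall back to the charge centroid of the
#' used pixels and are flagged.
#'
#' @param charges events x groups charge matrix.
#' @param tiling the `lasip_tiling`.
#' @param lrf the fitted `lrf_model` (pixels without a usable fit are never
#'   used as seed or neighbour).
#' @param cfg a `recon_config`.
#' @return data frame: `x`, `y`, `nll`, `seed`, `converged`.
#' @export
reconstruct_events <- function(charges, tiling, lrf, cfg = recon_config()) {
  if (is.null(dim(charges))) charges <- matrix(charges, nrow = 1)
  stopifnot(ncol(charges) == tiling$n_groups)
  ok <- lrf$ok & !is.na(lrf$params[, 1])
  if (!any(ok)) stop("no usable LRF fits")
  M <- min(cfg$M_rec, sum(ok))
  nb <- .neighbor_matrix_ok(tiling, M, ok)
  g <- tiling$groups
  res <- .cpp_reconstruct(charges, lrf$params, g$cx, g$cy, nb, ok,
                          cfg$r_rec, tiling$layout$pitch / 2, cfg$tol,
                          cfg$maxit)
  data.frame(x = res[, 1], y = res[, 2], nll = res[, 3],
             seed = as.integer(res[, 4]), converged = res[, 5] == 1)
}

# Neighbour matrix restricted to pixels with usable LRFs.  Rows of
# unusable seeds are filled with the usable neighbourhood anyway (they are
# never selected as seed).
.neighbor_matrix_ok <- function(tiling, k, ok) {
  g <- tiling$groups
  ids_ok <- g$gid[ok]
  t(vapply(g$gid, function(s) {
    d <- (g$cx[ids_ok] - g$cx[s])^2 + (g$cy[ids_ok] - g$cy[s])^2
    ids_ok[order(d, ids_ok)][seq_len(k)]
  }, integer(k)))
}

# Brute-force grid-search positioning (oracle used in tests): minimises the
# NLL on a regular grid of the given step within r_rec of the seed pixel.
grid_search_position <- function(q, tiling, lrf, cfg = recon_config(),
                                 step = 0.1) {
  ok <- lrf$ok & !is.na(lrf$params[, 1])
  qok <- q
  qok[!ok] <- -Inf
  seed <- which.max(qok)
  used <- .neighbor_matrix_ok(tiling, min(cfg$M_rec, sum(ok)), ok)[seed, ]
  cx <- tiling$groups$cx[seed]; cy <- tiling$groups$cy[seed]
  xs <- seq(cx - cfg$r_rec, cx + cfg$r_rec, by = step)
  ys <- seq(cy - cfg$r_rec, cy + cfg$r_rec, by = step)
  best <- c(NA, NA, Inf)
  for (y in ys) {
    if (abs(y - cy) > cfg$r_rec) next
    keep <- xs[(xs - cx)^2 + (y - cy)^2 <= cfg$r_rec^2]
    if (!length(keep)) next
    v <- vapply(keep, function(x)
      neg_log_likelihood(q[used], lrf, used, x, y), 0)
    i <- which.min(v)
    if (v[i] < best[3]) best <- c(keep[i], y, v[i])
  }
  list(x = best[1], y = best[2], nll = best[3], seed = seed, used = used)
}
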