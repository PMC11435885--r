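# End-to-end experiment orchestration: simulate -> noise -> calibrate ->
# reconstruct -> correct -> report, from a single configuration.

#' Build the calibration chain of one camera configuration
#'
#' Constructs the tiling, collects and fits the LRFs, reconstructs the
#' calibration grid to build the linearity map, and builds the flat-field
#' uniformity map.
#'
#' @param cfg an `optics_config` (with calibrated `intrinsic_sigma`).
#' @param model pixel configuration 1..8.
#' @param noise a `noise_config` applied to the measurement datasets (the
#'   LRF calibration itself is noiseless).
#' @param n_cal events per calibration node for the LRF samples.
#' @param n_lin events per node for the linearity map.
#' @param n_ffi flat-field events for the uniformity map.
#' @param recon a `recon_config`.
#' @param grid a [calibration_grid()].
#' @return list of class `camera_pipeline` with the tiling, LRF model,
#'   linearity and uniformity maps.
#' @export
build_pipeline <- function(cfg, model, noise = noise_config("none"),
                           n_cal = 200, n_lin = 20, n_ffi = 40000,
                           recon = recon_config(),
                           grid = calibration_grid()) {
  layout <- build_grid(lasip_models$grid[model], c(225, 225), 6, 0.25)
  tiling <- group_pixels(layout, model)
  samples <- collect_lrf_samples(cfg, tiling, grid, n_cal)
  lrf <- fit_bell(samples, tiling)
  # linearity: reconstruct the calibration nodes (noiseless beams)
  pos_cal <- grid[rep(seq_len(nrow(grid)), each = n_lin), ]
  counts <- .sample_group_events(cfg, tiling,
                                 cbind(pos_cal$x, pos_cal$y))
  rc <- reconstruct_events(counts, tiling, lrf, recon)
  lin <- build_linearity_map(grid, data.frame(j = pos_cal$j,
                                              x = rc$x, y = rc$y))
  # uniformity: flat field over the fiducial area, with the target noise
  span <- max(grid$x) - min(grid$x)
  fid <- span / 2 - (grid$x[2] - grid$x[1])
  ffi <- .reconstruct_source(cfg, tiling, lrf,
                             source_spec("flatfield", limits = c(fid, fid)),
                             n_ffi, noise, recon)
  ffi_corr <- apply_linearity(ffi$rec, lin)
  umap <- build_uniformity_map(ffi_corr, extent = c(-fid, fid, -fid, fid))
  structure(list(cfg = cfg, model = model, noise = noise, tiling = tiling,
                 lrf = lrf, linearity = lin, uniformity = umap,
                 recon = recon, grid = grid, fiducial = fid),
            class = "camera_pipeline")
}

# Simulate a source, photopeak-filter on the baseline-subtracted full sum,
# reconstruct the accepted events.  Returns true positions, reconstructed
# positions and the survival fractions.
.reconstruct_source <- function(cfg, tiling, lrf, spec, n, noise, recon) {
  ds <- simulate_group_dataset(cfg, tiling, spec, n, noise)
  ped <- if (!is.null(noise) && noise$dcr > 0)
    expected_dark_charge(tiling, noise) else NULL
  Q <- truncated_charge(ds$charges, ncol(ds$charges), ped)
  pf <- photopeak_filter(Q)
  keep <- pf$accepted
  rc <- reconstruct_events(ds$charges[keep, , drop = FALSE], tiling, lrf,
                           recon)
  list(true = ds$true[keep, , drop = FALSE], rec = cbind(rc$x, rc$y),
       recon = rc, accepted_fraction = mean(keep),
       converged_fraction = mean(rc$converged))
}

#' Simulate, reconstruct and correct a source with a calibrated pipeline
#'
#' @param pl a `camera_pipeline`.
#' @param spec a `source_spec`.
#' @param n number of events.
#' @return list with `true` positions, corrected reconstructed positions
#'   `rec`, and the photopeak/convergence survival fractions.
#' @export
reconstruct_source <- function(pl, spec, n) {
  out <- .reconstruct_source(pl$cfg, pl$tiling, pl$lrf, spec, n, pl$noise,
                             pl$recon)
  out$rec_raw <- out$rec
  out$rec <- apply_linearity(out$rec, pl$linearity)
  out
}

# Default capillary positions through interior pixel centres near the
# camera axis (the conservative d-hat = 0 choice).
center_capillary_positions <- function(tiling, k = 3, max_offset = 40) {
  g <- tiling$groups[!tiling$groups$partial, ]
  g <- g[abs(g$cx) <= max_offset & abs(g$cy) <= max_offset, ]
  cx <- sort(unique(round(g$cx, 6)))
  cx[order(abs(cx))][seq_len(min(k, length(cx)))]
}

#' Measure the intrinsic spatial resolution of a pipeline
#'
#' Simulates vertical capillaries through interior pixel centres,
#' reconstructs and corrects them, and pools the band FWHM values.
#'
#' @param pl a `camera_pipeline`.
#' @param x_caps capillary x positions; default up to 3 interior
#'   pixel-centre columns nearest the camera axis.
#' @param n_cap events per capillary.
#' @param y_range half-extent of the analysed y range, mm; default wide
#'   enough to cover at least three pixel rows.
#' @return list: per-capillary [capillary_resolution()] `samples`, pooled
#'   `mean` and `sd` over all bands, `n_bands`.
#' @export
measure_spatial_resolution <- function(pl, x_caps = NULL, n_cap = 2500,
                                       y_range = NULL) {
  if (is.null(y_range))
    y_range <- max(40, 1.55 * pixel_pitch(pl$tiling))
  if (is.null(x_caps))
    x_caps <- center_capillary_positions(pl$tiling, 3, 40)
  samples <- lapply(x_caps, function(xc) {
    src <- source_spec("capillary", x = xc, length = 2 * (y_range + 5))
    rr <- reconstruct_source(pl, src, n_cap)
    tryCatch(capillary_resolution(rr$rec, pl$tiling, xc, y_range,
                                  umap = pl$uniformity, min_bands = 1),
             error = function(e) NULL)
  })
  samples <- Filter(Negate(is.null), samples)
  fw <- unlist(lapply(samples, function(s) s$bands$fwhm))
  fw <- fw[is.finite(fw)]
  if (length(fw) < 3)
    stop("fewer than 3 valid projection bands across all capillaries")
  list(samples = samples, x_caps = x_caps, mean = mean(fw),
       sd = stats::sd(fw), n_bands = length(fw))
}

#' Run a full experiment from a configuration
#'
#' Configuration fields (all optional except `model`): `model` (1..8),
#' `noise` (preset name), `source` (kind plus its parameters), `seed`,
#' `n_events`, `n_cal`, `n_lin`, `n_ffi`, `target_er`, `intrinsic_sigma`
#' (skips calibration when given), `out` (output directory).
#'
#' @param config named list or path to a YAML file.
#' @return the output directory, invisibly; writes event tables, the LRF
#'   table, correction maps, images and a report table plus a manifest.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(model = 1, noise = "room", source = list(kind = "point"),
                   seed = 1, n_events = 5000, n_cal = 150, n_lin = 15,
                   n_ffi = 20000, target_er = 8.1, intrinsic_sigma = NULL,
                   out = "runs/experiment")
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  config <- utils::modifyList(defaults, config)
  if (!(config$model %in% 1:8)) stop("invalid field 'model': must be 1..8")
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok) unlink(config$out, recursive = TRUE))
  set.seed(config$seed)

  noise <- noise_config(config$noise)
  cfg <- optics_config()
  lay <- build_grid(lasip_models$grid[config$model], c(225, 225), 6, 0.25)
  tiling <- group_pixels(lay, config$model)
  if (is.null(config$intrinsic_sigma)) {
    cal_tl <- if (lasip_models$grid[config$model] == "square") tiling
              else group_pixels(build_grid("square", c(225, 225), 6, 0.25), 1)
    cfg$intrinsic_sigma <- calibrate_intrinsic(
      cfg, cal_tl, config$target_er, n_events = 3000, seed = config$seed)
  } else cfg$intrinsic_sigma <- config$intrinsic_sigma

  pl <- build_pipeline(cfg, config$model, noise, n_cal = config$n_cal,
                       n_lin = config$n_lin, n_ffi = config$n_ffi)
  write_tiling(tiling, file.path(config$out, "tiling.tsv"))
  write_lrf(pl$lrf, file.path(config$out, "lrf.tsv"))

  src <- do.call(source_spec, config$source)
  er <- measure_er(cfg, tiling, noise, config$n_events)
  utils::write.table(er$curve, file.path(config$out, "er_curve.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  rr <- reconstruct_source(pl, src, config$n_events)
  ev <- data.frame(true_x = rr$true[, 1], true_y = rr$true[, 2],
                   x = rr$rec[, 1], y = rr$rec[, 2],
                   nll = rr$recon$nll, seed_pixel = rr$recon$seed,
                   converged = rr$recon$converged)
  utils::write.table(ev, file.path(config$out, "events.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  fid <- pl$fiducial
  img <- make_image(rr$rec, 1, c(-fid, fid, -fid, fid))
  img <- apply_uniformity(img, pl$uniformity)
  utils::write.table(img$counts, file.path(config$out, "image.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  grDevices::png(file.path(config$out, "image.png"), 600, 600)
  graphics::image(img$xmid, img$ymid, img$counts, asp = 1,
                  xlab = "x [mm]", ylab = "y [mm]",
                  main = sprintf("model %d, %s noise, %s source",
                                 config$model, noise$preset, src$kind))
  grDevices::dev.off()

  report <- data.frame(model = config$model, noise = noise$preset,
                       er = er$er_opt, M_opt = er$M_opt,
                       equiv_sipm_opt = er$equiv_opt,
                       sr_mean = NA_real_, sr_sd = NA_real_,
                       accepted_fraction = rr$accepted_fraction,
                       converged_fraction = rr$converged_fraction,
                       intrinsic_sigma = cfg$intrinsic_sigma)
  if (src$kind == "capillary") {
    sr <- capillary_resolution(rr$rec, tiling, src$x,
                               y_range = max(40, 1.55 * pixel_pitch(tiling)),
                               umap = pl$uniformity)
    report$sr_mean <- sr$mean
    report$sr_sd <- sr$sd
  }
  utils::write.table(report, file.path(config$out, "report.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- list(config = config, seed = config$seed,
                   intrinsic_sigma = cfg$intrinsic_sigma,
                   r_version = R.version.string,
                   package_version = as.character(
                     utils::packageVersion("lasipcam")))
  jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  ok <- TRUE
  invisible(config$out)
}

#' Combine per-configuration reports into a comparison table
#'
#' @param reports list of report data frames (as written by
#'   [run_experiment()]) or paths to `report.tsv` files.
#' @return wide data frame: one row per model, energy resolution and
#'   spatial resolution columns per noise preset; missing combinations are
#'   left `NA`.
#' @export
compare_models <- function(reports) {
  dfs <- lapply(reports, function(r)
    if (is.character(r)) utils::read.table(r, header = TRUE, sep = "\t")
    else r)
  all <- do.call(rbind, lapply(dfs, function(d)
    d[, c("model", "noise", "er", "sr_mean", "sr_sd", "intrinsic_sigma")]))
  if (length(unique(round(all$intrinsic_sigma, 6))) > 1)
    stop("reports use different optics calibrations")
  presets <- c("none", "cooled", "room", "hot")
  models <- sort(unique(all$model))
  out <- data.frame(model = models)
  for (p in intersect(presets, unique(all$noise))) {
    m <- all[all$noise == p, ]
    out[[paste0("er_", p)]] <- m$er[match(models, m$model)]
    out[[paste0("sr_", p)]] <- m$sr_mean[match(models, m$model)]
  }
  out
}
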