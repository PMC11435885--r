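# Spatial-linearity and flat-field uniformity corrections.
#
# Pipeline order mirrors the reconstruction chain: raw positions ->
# event-wise linearity correction (displacement map interpolated from the
# calibration grid) -> image-wise uniformity correction (inverse
# normalised flat-field image).

#' Build the spatial-linearity correction map
#'
#' Compares the mean reconstructed position of every calibration node with
#' its true position and stores the displacement field on the calibration
#' lattice.
#'
#' @param grid a [calibration_grid()].
#' @param rec data frame with node index `j` and reconstructed `x`, `y`
#'   (one row per event).
#' @return list of class `linearity_map`: node coordinates `xs`, `ys` and
#'   displacement matrices `dx`, `dy` (rows follow `xs`, columns `ys`).
#' @export
build_linearity_map <- function(grid, rec) {
  missing <- setdiff(grid$j, unique(rec$j[is.finite(rec$x)]))
  if (length(missing))
    stop("calibration nodes not reconstructed: ",
         paste(utils::head(missing, 20), collapse = ", "))
  mx <- tapply(rec$x, rec$j, mean, na.rm = TRUE)[as.character(grid$j)]
  my <- tapply(rec$y, rec$j, mean, na.rm = TRUE)[as.character(grid$j)]
  xs <- sort(unique(grid$x))
  ys <- sort(unique(grid$y))
  ix <- match(grid$x, xs)
  iy <- match(grid$y, ys)
  dx <- dy <- matrix(NA_real_, length(xs), length(ys))
  dx[cbind(ix, iy)] <- mx - grid$x
  dy[cbind(ix, iy)] <- my - grid$y
  if (anyNA(dx)) stop("incomplete calibration lattice")
  structure(list(xs = xs, ys = ys, dx = dx, dy = dy),
            class = "linearity_map")
}

# Bilinear interpolation of a lattice field; coordinates outside the
# lattice are clamped (nearest-edge extrapolation).
.interp_lattice <- function(xs, ys, z, x, y) {
  x <- pmin(pmax(x, xs[1]), xs[length(xs)])
  y <- pmin(pmax(y, ys[1]), ys[length(ys)])
  i <- pmin(pmax(findInterval(x, xs), 1L), length(xs) - 1L)
  j <- pmin(pmax(findInterval(y, ys), 1L), length(ys) - 1L)
  tx <- (x - xs[i]) / (xs[i + 1L] - xs[i])
  ty <- (y - ys[j]) / (ys[j + 1L] - ys[j])
  z[cbind(i, j)] * (1 - tx) * (1 - ty) +
    z[cbind(i + 1L, j)] * tx * (1 - ty) +
    z[cbind(i, j + 1L)] * (1 - tx) * ty +
    z[cbind(i + 1L, j + 1L)] * tx * ty
}

#' Apply the linearity correction to positions
#'
#' Event-wise subtraction of the interpolated displacement; the number of
#' events is conserved.
#'
#' @param pos n x 2 matrix (or data frame with `x`, `y`).
#' @param map a `linearity_map`.
#' @return matrix of corrected positions.
#' @export
apply_linearity <- function(pos, map) {
  if (is.data.frame(pos)) pos <- cbind(pos$x, pos$y)
  cbind(pos[, 1] - .interp_lattice(map$xs, map$ys, map$dx, pos[, 1], pos[, 2]),
        pos[, 2] - .interp_lattice(map$xs, map$ys, map$dy, pos[, 1], pos[, 2]))
}

#' Histogram reconstructed positions into a camera image
#'
#' @param pos n x 2 matrix of positions.
#' @param binwidth bin width, mm.
#' @param extent `c(xmin, xmax, ymin, ymax)`, mm.
#' @return list of class `camera_image`: `counts` matrix, bin `xmid`,
#'   `ymid` and the extent.
#' @export
make_image <- function(pos, binwidth = 1, extent = c(-60, 60, -60, 60)) {
  if (is.data.frame(pos)) pos <- cbind(pos$x, pos$y)
  bx <- seq(extent[1], extent[2], by = binwidth)
  by <- seq(extent[3], extent[4], by = binwidth)
  keep <- is.finite(pos[, 1]) & is.finite(pos[, 2]) &
    pos[, 1] >= extent[1] & pos[, 1] < bx[length(bx)] &
    pos[, 2] >= extent[3] & pos[, 2] < by[length(by)]
  i <- findInterval(pos[keep, 1], bx, rightmost.closed = TRUE)
  j <- findInterval(pos[keep, 2], by, rightmost.closed = TRUE)
  counts <- matrix(0, length(bx) - 1L, length(by) - 1L)
  tb <- table(factor(i, levels = seq_len(length(bx) - 1L)),
              factor(j, levels = seq_len(length(by) - 1L)))
  counts[] <- as.numeric(tb)
  structure(list(counts = counts,
                 xmid = (bx[-1] + bx[-length(bx)]) / 2,
                 ymid = (by[-1] + by[-length(by)]) / 2,
                 binwidth = binwidth, extent = extent),
            class = "camera_image")
}

#' Build the flat-field uniformity map
#'
#' Bins the linearity-corrected flat-field positions over the fiducial
#' area, normalises the image to unit mean, clamps bins below the floor and
#' inverts it bin-wise.
#'
#' @param pos linearity-corrected flat-field positions (n x 2).
#' @param binwidth map bin width, mm.
#' @param extent fiducial area `c(xmin, xmax, ymin, ymax)`; default the
#'   calibration-lattice span minus one lattice spacing.
#' @param floor clamp floor as a fraction of the mean bin content.
#' @return list of class `uniformity_map`: multiplicative `map` matrix,
#'   bin centres, and the fraction of clamped bins.
#' @export
build_uniformity_map <- function(pos, binwidth = 6.5,
                                 extent = c(-58.5, 58.5, -58.5, 58.5),
                                 floor = 0.1) {
  img <- make_image(pos, binwidth, extent)
  mu <- mean(img$counts)
  if (mu <= 0) stop("empty flat-field image")
  if (mu < 5)
    stop("flat-field statistics too low to estimate the uniformity map")
  norm <- img$counts / mu
  clamped <- norm < floor
  norm[clamped] <- floor
  structure(list(map = 1 / norm, xmid = img$xmid, ymid = img$ymid,
                 binwidth = binwidth, extent = extent,
                 clamped_fraction = mean(clamped)),
            class = "uniformity_map")
}

#' Apply the uniformity correction to an image
#'
#' Multiplies each image bin by the map value interpolated at the bin
#' centre.
#'
#' @param image a `camera_image`.
#' @param umap a `uniformity_map`.
#' @return the corrected `camera_image` (float counts).
#' @export
apply_uniformity <- function(image, umap) {
  w <- outer(image$xmid, image$ymid, function(x, y)
    .interp_lattice(umap$xmid, umap$ymid, umap$map, x, y))
  image$counts <- image$counts * w
  image
}

# Coefficient of variation of the image over a central sub-area.
image_cov <- function(image, extent = NULL) {
  c0 <- image$counts
  if (!is.null(extent)) {
    kx <- image$xmid >= extent[1] & image$xmid <= extent[2]
    ky <- image$ymid >= extent[3] & image$ymid <= extent[4]
    c0 <- c0[kx, ky]
  }
  stats::sd(c0) / mean(c0)
}
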