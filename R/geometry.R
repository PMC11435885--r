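# SiPM grid construction and LASiP pixel grouping.
#
# Coordinates: camera centre at the origin, units mm, x right / y up.
# The SiPM lattice pitch is side + gap in both directions; the honeycomb
# layout is realised as horizontal rows at vertical pitch side + gap with
# odd rows shifted +pitch/2 in x, which gives every interior cell six
# lattice neighbours (two in-row, four in the adjacent rows).

#' Build a pixelated SiPM layout
#'
#' Tiles a rectangular region with 6 x 6 mm2 SiPM cells on either a square
#' grid or a row-offset honeycomb grid.
#'
#' @param grid_kind `"square"` or `"honeycomb"`.
#' @param region numeric length-2, instrumented width and height in mm.
#' @param sipm_side SiPM side length in mm.
#' @param gap gap between neighbouring SiPMs in mm.
#' @return An object of class `camera_layout`: a list with the grid kind,
#'   pitch, region and a data frame `cells` (id, col, row, x, y) in
#'   deterministic row-major order (lowest id at min-x, min-y).
#' @examples
#' lay <- build_grid("square", c(225, 225), 6, 0.25)
#' nrow(lay$cells)  # 1296
#' @export
build_grid <- function(grid_kind = c("square", "honeycomb"),
                       region = c(225, 225), sipm_side = 6, gap = 0.25) {
  grid_kind <- match.arg(grid_kind)
  stopifnot(length(region) == 2, all(region > 0), sipm_side > 0, gap >= 0)
  pitch <- sipm_side + gap
  W <- region[1]; H <- region[2]
  if (W < sipm_side + gap / 2 || H < sipm_side + gap / 2)
    stop("region smaller than one SiPM cell")
  n_fit <- function(offset) {
    # cells span [offset + i*pitch + gap/2, + side]; count those inside [0, W]
    max(0L, floor((W - offset - gap / 2 - sipm_side) / pitch) + 1L)
  }
  ny <- max(0L, floor((H - gap / 2 - sipm_side) / pitch) + 1L)
  if (ny < 1L) stop("region smaller than one SiPM cell")
  rows <- vector("list", ny)
  for (j in seq_len(ny) - 1L) {
    off <- if (grid_kind == "honeycomb" && j %% 2L == 1L) pitch / 2 else 0
    nx <- n_fit(off)
    if (nx < 1L) stop("region smaller than one SiPM cell")
    i <- seq_len(nx) - 1L
    rows[[j + 1L]] <- data.frame(
      col = i, row = j,
      x = -W / 2 + off + (i + 0.5) * pitch,
      y = -H / 2 + (j + 0.5) * pitch)
  }
  cells <- do.call(rbind, rows)
  cells <- cells[order(cells$row, cells$col), ]
  cells$id <- seq_len(nrow(cells))
  rownames(cells) <- NULL
  structure(list(grid_kind = grid_kind, region = region, side = sipm_side,
                 gap = gap, pitch = pitch,
                 cell_area = sipm_side^2,
                 cells = cells[, c("id", "col", "row", "x", "y")],
                 n_cells = nrow(cells)),
            class = "camera_layout")
}

#' @export
print.camera_layout <- function(x, ...) {
  cat(sprintf("<camera_layout> %s grid, %d SiPMs of %g mm (gap %g mm), region %g x %g mm\n",
              x$grid_kind, x$n_cells, x$side, x$gap, x$region[1], x$region[2]))
  invisible(x)
}

#' The eight studied pixel configurations
#'
#' SiPMs per pixel, pixel area, shape and the grid each configuration
#' requires.
#' @format data frame with columns `model`, `n_sipm`, `area`, `shape`,
#'   `grid`.
#' @export
lasip_models <- data.frame(
  model = 1:8,
  n_sipm = c(9L, 16L, 25L, 36L, 24L, 7L, 19L, 24L),
  area = c(324, 576, 900, 1296, 864, 252, 684, 864),
  shape = c("square", "square", "square", "square", "flower",
            "comb", "comb", "comb"),
  grid = c("square", "square", "square", "square", "square",
           "honeycomb", "honeycomb", "honeycomb"),
  stringsAsFactors = FALSE)

# Group templates as integer lattice offsets.  The flower-24 is the
# 4-fold-symmetric octagon with rows (2,4,6,6,4,2), which tiles the square
# lattice with translation lattice {(6,0),(3,4)}.  The combs are the
# symmetric hexagon-like row patterns (2,3,2), (3,4,5,4,3) and (4,5,6,5,4)
# on the offset lattice, expressed in axial coordinates; all three tile by
# translations.
.flower24_template <- local({
  rows <- list(`-3` = -1:0, `-2` = -2:1, `-1` = -3:2, `0` = -3:2,
               `1` = -2:1, `2` = -1:0)
  do.call(rbind, lapply(names(rows), function(r)
    cbind(dx = rows[[r]], dy = as.integer(r))))
})

.hex_template <- function(rad) {
  g <- expand.grid(q = -rad:rad, r = -rad:rad)
  g <- g[abs(g$q + g$r) <= rad, ]
  cbind(dx = g$q, dy = g$r)
}

.comb24_template <- local({
  rows <- list(`-2` = -1:2, `-1` = -2:2, `0` = -3:2, `1` = -3:1, `2` = -3:0)
  do.call(rbind, lapply(names(rows), function(r)
    cbind(dx = rows[[r]], dy = as.integer(r))))
})

.group_templates <- list(
  `5` = list(template = .flower24_template, t1 = c(6L, 0L), t2 = c(3L, 4L)),
  `6` = list(template = .hex_template(1L), t1 = c(2L, 1L), t2 = c(-1L, 3L)),
  `7` = list(template = .hex_template(2L), t1 = c(3L, 2L), t2 = c(-2L, 5L)),
  `8` = list(template = .comb24_template, t1 = c(3L, 3L), t2 = c(6L, -2L)))

# Assign integer lattice points (x, y) to translated copies of a template
# that tiles with translation lattice {t1, t2}.  Returns the anchor lattice
# point (as a key string "m,n") of the copy containing each input point.
.assign_template <- function(x, y, template, t1, t2) {
  D <- t1[1] * t2[2] - t1[2] * t2[1]
  aD <- abs(D)
  # residue of each template offset modulo the lattice (each occurs once)
  res_key <- function(px, py) {
    u <- ((t2[2] * px - t2[1] * py) %% aD)
    v <- ((-t1[2] * px + t1[1] * py) %% aD)
    u * aD + v
  }
  tkey <- res_key(template[, 1], template[, 2])
  if (anyDuplicated(tkey)) stop("template does not tile with given lattice")
  idx <- match(res_key(x, y), tkey)
  if (anyNA(idx)) stop("template does not cover the lattice")
  ax <- x - template[idx, 1]
  ay <- y - template[idx, 2]
  # anchor in lattice coordinates (exact integers)
  m <- (ax * t2[2] - ay * t2[1]) / D
  n <- (-ax * t1[2] + ay * t1[1]) / D
  paste(m, n, sep = ",")
}

#' Group SiPMs into LASiP pixels
#'
#' Partitions the cells of a layout into large-area pixels following one of
#' the eight studied configurations (four square block sizes, a flower
#' grouping on the square grid, and three comb groupings on the honeycomb
#' grid).  Groups clipped by the region boundary are kept and flagged
#' `partial`.
#'
#' @param layout a `camera_layout`.
#' @param model integer 1..8.
#' @return An object of class `lasip_tiling`: the layout, the model row,
#'   a `groups` data frame (gid, cx, cy, n_members, area, partial) and the
#'   per-cell group assignment `cell_gid`.
#' @export
group_pixels <- function(layout, model) {
  stopifnot(inherits(layout, "camera_layout"))
  if (!(model %in% 1:8)) stop("model must be in 1..8")
  info <- lasip_models[model, ]
  if (layout$grid_kind != info$grid)
    stop(sprintf("model %d requires a %s layout", model, info$grid))
  cells <- layout$cells
  if (model %in% 1:4) {
    k <- c(3L, 4L, 5L, 6L)[model]
    key <- paste(cells$col %/% k, cells$row %/% k, sep = ",")
  } else if (model == 5L) {
    tm <- .group_templates[["5"]]
    # anchor so one flower is centred on the camera centre
    c0 <- round(max(cells$col) / 2)
    key <- .assign_template(cells$col - c0, cells$row - c0,
                            tm$template, tm$t1, tm$t2)
  } else {
    tm <- .group_templates[[as.character(model)]]
    q <- cells$col - (cells$row - cells$row %% 2L) %/% 2L
    r <- cells$row
    j0 <- round(max(cells$row) / 2)
    q0 <- j0 - (j0 - j0 %% 2L) %/% 2L
    key <- .assign_template(q - q0, r - j0, tm$template, tm$t1, tm$t2)
  }
  sp <- split(seq_len(nrow(cells)), key)
  cx <- vapply(sp, function(i) mean(cells$x[i]), 0)
  cy <- vapply(sp, function(i) mean(cells$y[i]), 0)
  nm <- lengths(sp)
  ord <- order(round(cy, 6), round(cx, 6))
  sp <- sp[ord]; cx <- cx[ord]; cy <- cy[ord]; nm <- nm[ord]
  gid <- seq_along(sp)
  cell_gid <- integer(nrow(cells))
  for (g in gid) cell_gid[sp[[g]]] <- g
  groups <- data.frame(gid = gid, cx = cx, cy = cy,
                       n_members = as.integer(nm),
                       area = nm * layout$cell_area,
                       partial = nm < info$n_sipm)
  rownames(groups) <- NULL
  structure(list(model = model, shape = info$shape, n_sipm = info$n_sipm,
                 layout = layout, groups = groups, cell_gid = cell_gid,
                 members = sp, n_groups = length(gid)),
            class = "lasip_tiling")
}

#' @export
print.lasip_tiling <- function(x, ...) {
  cat(sprintf("<lasip_tiling> model %d (%s, %d SiPMs/pixel): %d groups (%d full) on %s grid\n",
              x$model, x$shape, x$n_sipm, x$n_groups,
              sum(!x$groups$partial), x$layout$grid_kind))
  invisible(x)
}

#' k nearest pixel groups by centroid distance
#'
#' @param tiling a `lasip_tiling`.
#' @param seed_gid group id whose neighbourhood is wanted.
#' @param k number of groups to return (including the seed itself).
#' @return Integer vector of `k` group ids ordered by ascending centroid
#'   distance from the seed centroid; ties broken by ascending id.
#' @export
nearest_groups <- function(tiling, seed_gid, k) {
  stopifnot(inherits(tiling, "lasip_tiling"), k >= 1,
            k <= tiling$n_groups, seed_gid %in% tiling$groups$gid)
  g <- tiling$groups
  d <- (g$cx - g$cx[seed_gid])^2 + (g$cy - g$cy[seed_gid])^2
  g$gid[order(d, g$gid)][seq_len(k)]
}

# Neighbour index matrix used by the reconstruction: row g holds the k
# nearest group ids of group g (g itself first).
neighbor_matrix <- function(tiling, k) {
  t(vapply(tiling$groups$gid, function(g) nearest_groups(tiling, g, k),
           integer(k)))
}

# Sum a per-cell count matrix (events x cells) into per-group charges.
group_charges <- function(counts, tiling) {
  stopifnot(ncol(counts) == tiling$layout$n_cells)
  out <- t(rowsum(t(counts), group = tiling$cell_gid, reorder = TRUE))
  colnames(out) <- NULL
  out
}

#' Write / read a tiling as a structured text file
#'
#' Serialises cell ids, centres and group membership so reconstructions are
#' reproducible without re-deriving the geometry.
#' @param tiling a `lasip_tiling`.
#' @param path output file.
#' @export
write_tiling <- function(tiling, path) {
  lay <- tiling$layout
  hdr <- c(sprintf("# lasip_tiling model=%d grid=%s side=%g gap=%g region=%gx%g",
                   tiling$model, lay$grid_kind, lay$side, lay$gap,
                   lay$region[1], lay$region[2]))
  df <- cbind(lay$cells, gid = tiling$cell_gid)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tiling
#' @export
read_tiling <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec(
    "model=(\\d+) grid=(\\S+) side=(\\S+) gap=(\\S+) region=(\\S+)x(\\S+)", hdr))[[1]]
  lay <- build_grid(m[3], as.numeric(c(m[6], m[7])), as.numeric(m[4]),
                    as.numeric(m[5]))
  tl <- group_pixels(lay, as.integer(m[2]))
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L)
  if (!identical(tl$cell_gid, df$gid))
    stop("stored grouping does not match re-derived geometry")
  tl
}
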