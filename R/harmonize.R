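#' Upscale a raster by block means
#'
#' Each coarse cell is the mean of its `factor^2` fine member cells,
#' no-data members ignored; a coarse cell is no-data only when every
#' member is. Grids whose dimensions are not divisible by `factor` are
#' padded with no-data on the south/east edges first.
#'
#' @param r An [es_raster()].
#' @param factor Integer aggregation factor, at least 2.
#' @return An [es_raster()] on the coarse grid (same origin, cell size
#'   multiplied by `factor`).
#' @export
upscale_mean <- function(r, factor) {
  factor <- as.integer(factor)
  if (factor < 2) stop("factor must be >= 2")
  v <- r$values
  nr <- nrow(v); nc <- ncol(v)
  nr_pad <- ceiling(nr / factor) * factor
  nc_pad <- ceiling(nc / factor) * factor
  if (nr_pad > nr || nc_pad > nc) {
    vp <- matrix(NA_real_, nr_pad, nc_pad)
    vp[seq_len(nr), seq_len(nc)] <- v
    v <- vp
  }
  cr <- nr_pad / factor; cc <- nc_pad / factor
  # group fine cells by coarse block index and average, NA-aware
  bi <- (rep(seq_len(nr_pad), times = nc_pad) - 1L) %/% factor
  bj <- (rep(seq_len(nc_pad), each = nr_pad) - 1L) %/% factor
  block <- bi + cr * bj + 1L
  sums <- tapply(ifelse(is.na(v), 0, v), block, sum)
  cnts <- tapply(!is.na(v), block, sum)
  out <- as.numeric(sums) / as.numeric(cnts)  # NaN where count 0
  out[cnts == 0] <- NA
  g <- r$grid
  es_raster(matrix(out, cr, cc),
            es_grid(g$origin_lon, g$origin_lat, g$cell_size * factor, cr, cc))
}

#' Downscale a raster by bilinear interpolation
#'
#' Fine cell centers are interpolated linearly from the four nearest
#' coarse cell centers, giving a smooth transition between coarse cells.
#' Beyond the outermost centers, coordinates are clamped to the nearest
#' center (constant extrapolation at the edges). A fine cell is no-data
#' when any coarse center that contributes with positive weight is
#' no-data.
#'
#' @param r An [es_raster()].
#' @param factor Integer refinement factor, at least 2.
#' @return An [es_raster()] on the fine grid.
#' @export
downscale_bilinear <- function(r, factor) {
  factor <- as.integer(factor)
  if (factor < 2) stop("factor must be >= 2")
  v <- r$values
  nr <- nrow(v); nc <- ncol(v)
  fr <- nr * factor; fc <- nc * factor
  # fine center position in coarse index coordinates (1-based)
  pos <- function(i_fine) (i_fine - 0.5) / factor + 0.5
  interp_axis <- function(n_fine, n_coarse) {
    p <- pmin(pmax(pos(seq_len(n_fine)), 1), n_coarse)
    lo <- pmin(floor(p), n_coarse - 1L)
    if (n_coarse == 1L) lo <- rep(1L, n_fine)
    frac <- p - lo
    list(lo = as.integer(lo), frac = frac)
  }
  ax_r <- interp_axis(fr, nr)
  ax_c <- interp_axis(fc, nc)
  out <- matrix(NA_real_, fr, fc)
  wr1 <- 1 - ax_r$frac; wr2 <- ax_r$frac
  wc1 <- 1 - ax_c$frac; wc2 <- ax_c$frac
  r1 <- ax_r$lo; r2 <- pmin(ax_r$lo + 1L, nr)
  c1 <- ax_c$lo; c2 <- pmin(ax_c$lo + 1L, nc)
  v11 <- v[r1, c1, drop = FALSE]; v21 <- v[r2, c1, drop = FALSE]
  v12 <- v[r1, c2, drop = FALSE]; v22 <- v[r2, c2, drop = FALSE]
  W11 <- outer(wr1, wc1); W21 <- outer(wr2, wc1)
  W12 <- outer(wr1, wc2); W22 <- outer(wr2, wc2)
  zero_na <- function(m) ifelse(is.na(m), 0, m)
  out <- zero_na(v11) * W11 + zero_na(v21) * W21 +
    zero_na(v12) * W12 + zero_na(v22) * W22
  bad <- (is.na(v11) & W11 > 0) | (is.na(v21) & W21 > 0) |
    (is.na(v12) & W12 > 0) | (is.na(v22) & W22 > 0)
  out[bad] <- NA
  g <- r$grid
  es_raster(out, es_grid(g$origin_lon, g$origin_lat, g$cell_size / factor, fr, fc))
}

#' Align rasters onto a target grid
#'
#' Brings every raster onto `target`: integer resolution ratios are
#' resolved by [upscale_mean()] (raster finer than target) or
#' [downscale_bilinear()] (raster coarser), then layers are clipped or
#' padded with no-data so all share the target extent; cell origins must
#' line up on whole cells. All rasters are assumed to share one
#' geographic CRS. The result records the per-cell count of contributing
#' models.
#'
#' @param rasters Named list of [es_raster()] (names become model ids).
#' @param target An [es_grid()].
#' @return An [es_stack()] on `target`.
#' @export
align <- function(rasters, target) {
  if (length(rasters) == 0) stop("empty raster list")
  if (is.null(names(rasters))) {
    names(rasters) <- sprintf("m%02d", seq_along(rasters))
  }
  aligned <- lapply(rasters, function(r) {
    ratio <- r$grid$cell_size / target$cell_size
    if (abs(ratio - round(ratio)) < 1e-9 && round(ratio) >= 2) {
      r <- downscale_bilinear(r, round(ratio))
    } else if (abs(1 / ratio - round(1 / ratio)) < 1e-9 && round(1 / ratio) >= 2) {
      r <- upscale_mean(r, round(1 / ratio))
    } else if (abs(ratio - 1) > 1e-9) {
      stop("non-integer resolution ratio between raster and target grid")
    }
    g <- r$grid
    off_c <- (g$origin_lon - target$origin_lon) / target$cell_size
    off_r <- (target$origin_lat - g$origin_lat) / target$cell_size
    if (abs(off_c - round(off_c)) > 1e-6 || abs(off_r - round(off_r)) > 1e-6) {
      stop("raster origin not aligned to target grid cells")
    }
    off_c <- round(off_c); off_r <- round(off_r)
    out <- matrix(NA_real_, target$n_rows, target$n_cols)
    src_rows <- seq_len(g$n_rows); src_cols <- seq_len(g$n_cols)
    dst_rows <- src_rows + off_r; dst_cols <- src_cols + off_c
    keep_r <- dst_rows >= 1 & dst_rows <= target$n_rows
    keep_c <- dst_cols >= 1 & dst_cols <= target$n_cols
    out[dst_rows[keep_r], dst_cols[keep_c]] <-
      r$values[src_rows[keep_r], src_cols[keep_c]]
    es_raster(out, target)
  })
  es_stack(aligned)
}

#' Mask a raster by land-use classes
#'
#' Used to cut carbon layers down to woody (fuelwood) or grassland
#' (forage) proxies: cells whose mask class is outside `keep_classes`
#' become no-data, all others pass through unchanged.
#'
#' @param r An [es_raster()].
#' @param mask An [es_raster()] of integer classes on the same grid.
#' @param keep_classes Vector of class codes to retain.
#' @return The masked [es_raster()].
#' @export
apply_landuse_mask <- function(r, mask, keep_classes) {
  if (!same_grid(r$grid, mask$grid)) stop("mask grid does not match raster grid")
  v <- r$values
  v[!(mask$values %in% keep_classes)] <- NA
  es_raster(v, r$grid)
}
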