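#' Grid specification
#'
#' Describes a regular geographic grid with cell-center registration:
#' row 1 at the northern edge, column 1 at the western edge, x increasing
#' east and y decreasing south. Extents are half-open intervals so that
#' adjoining grids never double-count a cell boundary.
#'
#' @param origin_lon,origin_lat Coordinates (degrees) of the upper-left
#'   corner of the grid (the outer corner, not the first cell center).
#' @param cell_size Cell edge length in degrees; must be positive.
#' @param n_rows,n_cols Grid dimensions.
#' @return An object of class `es_grid`.
#' @export
es_grid <- function(origin_lon = 0, origin_lat = 0, cell_size = 1,
                    n_rows, n_cols) {
  stopifnot(cell_size > 0, n_rows >= 1, n_cols >= 1)
  structure(
    list(origin_lon = origin_lon, origin_lat = origin_lat,
         cell_size = cell_size, n_rows = as.integer(n_rows),
         n_cols = as.integer(n_cols)),
    class = "es_grid"
  )
}

#' @export
format.es_grid <- function(x, ...) {
  sprintf("<es_grid %d x %d @ %g deg, origin (%g, %g)>",
          x$n_rows, x$n_cols, x$cell_size, x$origin_lon, x$origin_lat)
}

#' @export
print.es_grid <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-12))
}

#' Raster layer
#'
#' A 2-D numeric grid plus a grid specification. No-data cells are stored
#' as `NA`; true zeros are data and participate in every statistic,
#' whereas `NA` cells are ignored.
#'
#' @param values Numeric matrix (rows north to south).
#' @param grid An [es_grid()]; defaults to a unit grid matching `values`.
#' @return An object of class `es_raster`.
#' @export
es_raster <- function(values, grid = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(grid)) {
    grid <- es_grid(n_rows = nrow(values), n_cols = ncol(values))
  }
  stopifnot(inherits(grid, "es_grid"),
            nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
  if (any(is.infinite(values))) {
    stop("raster values must be finite or NA (no-data)")
  }
  structure(list(values = values, grid = grid), class = "es_raster")
}

#' @export
print.es_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<es_raster %s; %d data cells, %d no-data>\n",
              format(x$grid), sum(!is.na(v)), sum(is.na(v))))
  if (sum(!is.na(v)) > 0) {
    cat(sprintf("  range [%g, %g]\n", min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  }
  invisible(x)
}

#' No-data mask of a raster
#'
#' @param r An [es_raster()].
#' @return Logical matrix, `TRUE` where the cell carries no data.
#' @export
nodata_mask <- function(r) is.na(r$values)

#' Cell-center coordinates
#'
#' @param grid An [es_grid()].
#' @return A data.frame with columns `row`, `col`, `lon`, `lat`, one row
#'   per cell in column-major cell-index order (`cell = row + (col-1)*n_rows`).
#' @export
cell_centers <- function(grid) {
  rows <- seq_len(grid$n_rows)
  cols <- seq_len(grid$n_cols)
  data.frame(
    row = rep(rows, times = grid$n_cols),
    col = rep(cols, each = grid$n_rows),
    lon = grid$origin_lon + (rep(cols, each = grid$n_rows) - 0.5) * grid$cell_size,
    lat = grid$origin_lat - (rep(rows, times = grid$n_cols) - 0.5) * grid$cell_size
  )
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format with an explicit NODATA tag. The
#' cell-center registration and row order of [es_grid()] map onto the
#' standard `xllcorner`/`yllcorner` header.
#'
#' @param r An [es_raster()].
#' @param path Output file path (conventionally `.asc`).
#' @param nodata Sentinel written for no-data cells.
#' @return `path`, invisibly.
#' @export
write_asc <- function(r, path, nodata = -9999) {
  g <- r$grid
  hdr <- c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.10g", g$origin_lon),
    sprintf("yllcorner %.10g", g$origin_lat - g$n_rows * g$cell_size),
    sprintf("cellsize %.10g", g$cell_size),
    sprintf("NODATA_value %.10g", nodata)
  )
  v <- r$values
  v[is.na(v)] <- nodata
  body <- apply(v, 1, function(row) paste(sprintf("%.10g", row), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File written by [write_asc()] (or any conforming .asc).
#' @return An [es_raster()] with the NODATA sentinel mapped back to `NA`.
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  n_rows <- hdr$nrows; n_cols <- hdr$ncols
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  stopifnot(length(vals) == n_rows * n_cols)
  m <- matrix(vals, nrow = n_rows, ncol = n_cols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  grid <- es_grid(origin_lon = hdr$xllcorner,
                  origin_lat = hdr$yllcorner + n_rows * hdr$cellsize,
                  cell_size = hdr$cellsize, n_rows = n_rows, n_cols = n_cols)
  es_raster(m, grid)
}

#' Stack of model rasters on one grid
#'
#' @param layers Named list of [es_raster()] objects sharing one grid; the
#'   names are model ids.
#' @return An object of class `es_stack` carrying the layers plus the
#'   per-cell count `n_models` of non-no-data layers.
#' @export
es_stack <- function(layers) {
  stopifnot(length(layers) >= 1)
  ids <- names(layers)
  if (is.null(ids) || any(ids == "") || anyDuplicated(ids)) {
    stop("layers must carry unique, non-empty model ids as names")
  }
  g <- layers[[1]]$grid
  for (l in layers) {
    if (!same_grid(l$grid, g)) stop("all layers must share one grid")
  }
  counts <- Reduce(`+`, lapply(layers, function(l) !is.na(l$values)))
  structure(list(layers = layers, grid = g,
                 n_models = es_raster(counts * 1.0, g)),
            class = "es_stack")
}

#' @export
print.es_stack <- function(x, ...) {
  cat(sprintf("<es_stack of %d layers: %s; %s>\n", length(x$layers),
              paste(names(x$layers), collapse = ", "), format(x$grid)))
  invisible(x)
}
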