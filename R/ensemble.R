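#' Fit double-sided Winsorising normalization cuts
#'
#' Stores the lower and upper percentile cut values (defaults 2.5% and
#' 97.5%) of the finite data values. Percentiles use linear interpolation
#' between order statistics (`stats::quantile` type 7); no-data values
#' are excluded from the fit.
#'
#' @param values Numeric vector, matrix, or [es_raster()].
#' @param lower_pct,upper_pct Percentile cut points, `lower_pct < upper_pct`.
#' @return An object of class `es_winsor` with elements `lower`, `upper`,
#'   `lower_pct`, `upper_pct`.
#' @export
winsorise_fit <- function(values, lower_pct = 2.5, upper_pct = 97.5) {
  stopifnot(lower_pct < upper_pct)
  if (inherits(values, "es_raster")) values <- values$values
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  if (length(v) < 2 || length(unique(v)) < 2) {
    stop("degenerate input: need at least 2 distinct finite values")
  }
  q <- stats::quantile(v, c(lower_pct, upper_pct) / 100,
                       names = FALSE, type = 7)
  structure(list(lower = q[1], upper = q[2],
                 lower_pct = lower_pct, upper_pct = upper_pct),
            class = "es_winsor")
}

#' Apply fitted Winsorising cuts
#'
#' Maps `v` to `clip((v - lower) / (upper - lower), 0, 1)`: values at or
#' below the lower cut become exactly 0, values at or above the upper cut
#' become exactly 1, no-data is preserved.
#'
#' @param values Numeric vector, matrix, or [es_raster()].
#' @param params An `es_winsor` from [winsorise_fit()].
#' @return Normalized object of the same shape/class as `values`.
#' @export
winsorise_apply <- function(values, params) {
  stopifnot(inherits(params, "es_winsor"))
  if (params$upper <= params$lower) stop("degenerate cuts: upper <= lower")
  tx <- function(v) pmin(pmax((v - params$lower) /
                                (params$upper - params$lower), 0), 1)
  if (inherits(values, "es_raster")) {
    es_raster(tx(values$values), values$grid)
  } else {
    tx(values)
  }
}

#' Winsorise a vector or raster in one step
#'
#' Convenience wrapper: fit the percentile cuts on the data values and
#' apply them, as done to every model layer and every validation vector
#' before scoring.
#'
#' @inheritParams winsorise_fit
#' @return Normalized object in \[0, 1\].
#' @export
winsorise <- function(values, lower_pct = 2.5, upper_pct = 97.5) {
  winsorise_apply(values, winsorise_fit(values, lower_pct, upper_pct))
}

#' Normalize every layer of a stack
#'
#' @param stack An [es_stack()].
#' @inheritParams winsorise_fit
#' @return An [es_stack()] whose layers are Winsorised to \[0, 1\].
#' @export
normalize_stack <- function(stack, lower_pct = 2.5, upper_pct = 97.5) {
  es_stack(lapply(stack$layers, winsorise,
                  lower_pct = lower_pct, upper_pct = upper_pct))
}

#' Build a per-cell committee ensemble with uncertainty layers
#'
#' The ensemble value at each cell is the median (or mean) over the
#' models that carry data there; true zeros contribute, no-data layers
#' are ignored. The per-cell spread is reported as the standard error of
#' the mean, `sd(x) / sqrt(n(x))` with the sample (n-1) standard
#' deviation; cells with a single contributing model get no-data SEM
#' (the sample sd is undefined there), and cells with no contributing
#' model are no-data throughout.
#'
#' A per-model weight vector turns the mean statistic into a weighted
#' cell statistic (the plug-in point for weighted-ensemble variants);
#' weights are renormalized per cell over the contributing models.
#'
#' @param stack An [es_stack()] of normalized layers.
#' @param statistic `"median"` or `"mean"`.
#' @param weights Optional numeric vector, one weight per layer (mean
#'   statistic only).
#' @return An object of class `es_ensemble`: `values`, `sem`, `n_models`
#'   rasters plus the statistic label.
#' @export
build_ensemble <- function(stack, statistic = c("median", "mean"),
                           weights = NULL) {
  statistic <- match.arg(statistic)
  K <- length(stack$layers)
  if (K == 0) stop("empty stack")
  g <- stack$grid
  arr <- vapply(stack$layers, function(l) l$values,
                matrix(0, g$n_rows, g$n_cols))
  dim(arr) <- c(g$n_rows * g$n_cols, K)
  n <- rowSums(!is.na(arr))
  if (statistic == "median") {
    if (!is.null(weights)) stop("weights are supported for the mean statistic")
    vals <- apply(arr, 1, stats::median, na.rm = TRUE)
  } else if (is.null(weights)) {
    vals <- rowMeans(arr, na.rm = TRUE)
  } else {
    stopifnot(length(weights) == K, all(weights >= 0), sum(weights) > 0)
    w <- matrix(weights, nrow(arr), K, byrow = TRUE)
    w[is.na(arr)] <- 0
    vals <- rowSums(arr * w, na.rm = TRUE) / rowSums(w)
  }
  vals[n == 0] <- NA
  sdv <- apply(arr, 1, function(x) stats::sd(x[!is.na(x)]))
  sem <- sdv / sqrt(n)
  sem[n <= 1] <- NA
  to_r <- function(x) es_raster(matrix(x, g$n_rows, g$n_cols), g)
  structure(list(statistic = statistic, values = to_r(vals),
                 sem = to_r(sem), n_models = to_r(n * 1.0)),
            class = "es_ensemble")
}

#' @export
print.es_ensemble <- function(x, ...) {
  cat(sprintf("<es_ensemble (%s) on %s>\n", x$statistic, format(x$values$grid)))
  invisible(x)
}

#' Renormalize an ensemble to span the full 0-1 range
#'
#' Min-max rescales the ensemble value layer so its minimum maps to 0
#' and its maximum to 1. The SEM and model-count layers are left on
#' their original scales.
#'
#' @param layer An `es_ensemble`.
#' @return The rescaled `es_ensemble`.
#' @export
renormalize_full_range <- function(layer) {
  v <- layer$values$values
  rng <- range(v, na.rm = TRUE)
  if (!is.finite(rng[1]) || rng[1] == rng[2]) {
    stop("degenerate ensemble: constant or empty value layer")
  }
  layer$values <- es_raster((v - rng[1]) / (rng[2] - rng[1]),
                            layer$values$grid)
  layer
}

#' Aggregate a raster over catchment or country polygons
#'
#' Per polygon, the sum (the within-catchment accumulation used for
#' gridded water estimates) or the maximum (the value at the assumed
#' flow-out point of accumulated-flow layers) of the data cells inside
#' it; no-data cells are ignored. Polygons containing no data cell get
#' `NA` and are flagged.
#'
#' @param r An [es_raster()].
#' @param polygons An `es_units` table (polygon/catchment kind) on the
#'   same grid.
#' @param mode `"sum"` or `"max"`.
#' @return Named numeric vector, one value per polygon, with attribute
#'   `"n_missing"` counting polygons without data.
#' @export
catchment_aggregate <- function(r, polygons, mode = c("sum", "max")) {
  mode <- match.arg(mode)
  stopifnot(same_grid(r$grid, attr(polygons, "grid")))
  v <- as.vector(r$values)
  out <- vapply(polygons$cells, function(cs) {
    x <- v[cs]
    x <- x[!is.na(x)]
    if (length(x) == 0) return(NA_real_)
    if (mode == "sum") sum(x) else max(x)
  }, numeric(1))
  names(out) <- polygons$unit_id
  attr(out, "n_missing") <- sum(is.na(out))
  out
}
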