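#' Extract predicted values at validation units
#'
#' Three extraction modes mirror how gridded predictions are compared to
#' point, polygon/country and weir-catchment references:
#' * `polygon_sum` — sum of the data cells intersecting the unit;
#' * `point_value` — the value of the cell containing the unit's location;
#' * `max_within_radius` — the maximum data value within `radius`
#'   degrees of the unit's location (the flow-routing correction for
#'   accumulated-flow layers; the classic radius is 0.041665°, five cell
#'   widths at 0.008333°), never exceeding the unit's own polygon when
#'   one is supplied.
#'
#' Units without any data cell get `NA`; callers drop them listwise so
#' every predictor is scored on identical units.
#'
#' @param r An [es_raster()].
#' @param vs An `es_units` validation set on the same grid.
#' @param mode Extraction mode (see above).
#' @param radius Radius in degrees, required for `max_within_radius`.
#' @return Numeric vector of predictions aligned 1:1 with `vs`, with
#'   attributes `"label"` and `"n_missing"`.
#' @export
extract_predictions <- function(r, vs,
                                mode = c("polygon_sum", "point_value",
                                         "max_within_radius"),
                                radius = NULL, label = "predictor") {
  mode <- match.arg(mode)
  g <- r$grid
  stopifnot(same_grid(g, attr(vs, "grid")))
  v <- as.vector(r$values)
  cc <- cell_centers(g)
  n <- nrow(vs)

  loc_cell <- function(i) {
    # catchments carry a designated pour point; fall back to the centroid
    if (!is.null(vs$pour_cell) && !is.na(vs$pour_cell[i])) return(vs$pour_cell[i])
    col <- pmin(pmax(ceiling((vs$lon[i] - g$origin_lon) / g$cell_size), 1), g$n_cols)
    row <- pmin(pmax(ceiling((g$origin_lat - vs$lat[i]) / g$cell_size), 1), g$n_rows)
    row + (col - 1L) * g$n_rows
  }

  out <- vapply(seq_len(n), function(i) {
    if (mode == "polygon_sum") {
      x <- v[vs$cells[[i]]]
      x <- x[!is.na(x)]
      if (length(x) == 0) NA_real_ else sum(x)
    } else if (mode == "point_value") {
      v[loc_cell(i)]
    } else {
      if (is.null(radius)) stop("radius required for max_within_radius")
      cell <- loc_cell(i)
      if (radius <= 0) return(v[cell])
      d <- sqrt((cc$lon - cc$lon[cell])^2 + (cc$lat - cc$lat[cell])^2)
      cand <- which(d <= radius + 1e-12)
      if (vs$kind[i] %in% c("polygon", "catchment")) {
        cand <- intersect(cand, vs$cells[[i]])
      }
      x <- v[cand]
      x <- x[!is.na(x)]
      if (length(x) == 0) NA_real_ else max(x)
    }
  }, numeric(1))
  attr(out, "label") <- label
  attr(out, "n_missing") <- sum(is.na(out))
  out
}

#' Inverse-of-deviance accuracy
#'
#' For normalized observed values `X(x)` and predictions `Y(x)`, the
#' overall accuracy is
#' `D = 1 - (1/n) * sum |X(x) - Y(x)|`,
#' i.e. one minus the mean absolute deviation; per-point accuracies are
#' `1 - |X(x) - Y(x)|`. Spearman's rank correlation is reported as the
#' alternative, ranking-based accuracy measure.
#'
#' @param X Observed (validation) vector, normalized to \[0, 1\].
#' @param Y Prediction vector, same length and order.
#' @param label Provenance label for the predictor.
#' @return An object of class `es_accuracy`: `per_point`, `overall`,
#'   `spearman_rho`, `n`, `label`.
#' @export
deviance_accuracy <- function(X, Y, label = attr(Y, "label") %||% "predictor") {
  if (length(X) != length(Y)) stop("X and Y must have equal length")
  if (length(X) < 2) stop("need at least 2 units")
  if (anyNA(X) || anyNA(Y)) stop("missing values: drop unscored units first")
  if (any(X < 0 | X > 1) || any(Y < 0 | Y > 1)) {
    stop("inputs must be normalized to [0, 1]")
  }
  pp <- 1 - abs(X - Y)
  rho <- suppressWarnings(stats::cor(X, Y, method = "spearman"))
  structure(list(per_point = pp, overall = mean(pp), spearman_rho = rho,
                 n = length(X), label = label),
            class = "es_accuracy")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.es_accuracy <- function(x, ...) {
  cat(sprintf("<es_accuracy %s: D = %.4f, Spearman rho = %.3f, n = %d>\n",
              x$label, x$overall, x$spearman_rho, x$n))
  invisible(x)
}

#' Winsorise and score a raw prediction vector
#'
#' Applies the same double-sided Winsorising protocol to the observed and
#' predicted vectors (as is done for validation data and model outputs
#' alike) and scores the result with [deviance_accuracy()]. Units where
#' either side is missing are dropped, with the count recorded.
#'
#' @param X_raw,Y_raw Observed and predicted vectors on native scales.
#' @param label Predictor label.
#' @return An `es_accuracy` with attribute `"n_dropped"`.
#' @export
score_predictor <- function(X_raw, Y_raw, label = attr(Y_raw, "label") %||% "predictor") {
  keep <- !is.na(X_raw) & !is.na(Y_raw)
  acc <- deviance_accuracy(winsorise(X_raw[keep]), winsorise(Y_raw[keep]),
                           label = label)
  attr(acc, "n_dropped") <- sum(!keep)
  acc
}

#' Hochberg step-up multiple-testing correction
#'
#' Orders the p values ascending and rejects hypotheses `1..k` for the
#' largest `k` with `p(k) <= alpha / (m - k + 1)`. `m` may exceed the
#' number of supplied p values when the battery size is fixed a priori
#' (e.g. 5 comparisons per service, or 8 driver tests per service).
#'
#' @param p Vector of p values in \[0, 1\].
#' @param alpha Family-wise significance level.
#' @param m Number of tests in the family (default `length(p)`).
#' @return Logical rejection flags in the input order.
#' @export
hochberg_correct <- function(p, alpha = 0.05, m = length(p)) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stop("invalid p values")
  if (m < length(p)) stop("m must be at least length(p)")
  ord <- order(p)
  ps <- p[ord]
  k_ok <- which(ps <= alpha / (m - seq_along(ps) + 1))
  reject <- logical(length(p))
  if (length(k_ok) > 0) reject[ord[seq_len(max(k_ok))]] <- TRUE
  reject
}

#' Bootstrap comparison of predictor accuracies
#'
#' Repeatedly subsamples the validation units (without replacement by
#' default: a 10% fraction, or a fixed count such as 100 for
#' country-level sets), scores *every* predictor on the identical
#' resample, and compares predictors by paired t tests on the per-run
#' accuracy differences, Hochberg-corrected across the pairwise battery.
#'
#' @param predictors Named list of normalized prediction vectors, all
#'   aligned with `X`.
#' @param X Normalized observed vector.
#' @param n_runs Number of bootstrap runs (>= 2; the reference protocol
#'   uses 1000).
#' @param sample_rule `"fraction"` or `"fixed"`.
#' @param sample_size Fraction (e.g. 0.10) or fixed count (e.g. 100),
#'   according to `sample_rule`.
#' @param replace Resample with replacement instead of subsampling.
#' @param alpha Level for the Hochberg-corrected flags.
#' @param m Family size for the Hochberg correction (default: number of
#'   pairwise comparisons).
#' @return An object of class `es_comparison`: per-run accuracy matrix
#'   (`runs`), per-predictor mean/sd, and a pairwise table with mean
#'   differences, t statistics, p values and corrected flags.
#' @export
bootstrap_compare <- function(predictors, X, n_runs = 1000,
                              sample_rule = c("fraction", "fixed"),
                              sample_size = 0.10, replace = FALSE,
                              alpha = 0.05, m = NULL) {
  sample_rule <- match.arg(sample_rule)
  if (length(predictors) < 2) stop("need at least 2 predictors")
  if (n_runs < 2) stop("n_runs must be >= 2")
  ids <- names(predictors) %||% sprintf("p%d", seq_along(predictors))
  names(predictors) <- ids
  n <- length(X)
  keep <- !is.na(X) & Reduce(`&`, lapply(predictors, function(y) !is.na(y)))
  X <- X[keep]
  predictors <- lapply(predictors, function(y) y[keep])
  n <- length(X)
  k <- if (sample_rule == "fraction") max(2L, round(sample_size * n))
       else as.integer(sample_size)
  if (k < 2 || (!replace && k > n)) stop("invalid bootstrap sample size")

  runs <- matrix(NA_real_, n_runs, length(predictors),
                 dimnames = list(NULL, ids))
  for (b in seq_len(n_runs)) {
    idx <- sample.int(n, k, replace = replace)
    for (j in seq_along(predictors)) {
      runs[b, j] <- 1 - mean(abs(X[idx] - predictors[[j]][idx]))
    }
  }

  combos <- utils::combn(ids, 2)
  pair <- data.frame(a = combos[1, ], b = combos[2, ],
                     stringsAsFactors = FALSE)
  pair$mean_diff <- NA_real_; pair$t <- NA_real_; pair$p <- NA_real_
  for (i in seq_len(nrow(pair))) {
    d <- runs[, pair$a[i]] - runs[, pair$b[i]]
    pair$mean_diff[i] <- mean(d)
    if (stats::sd(d) == 0) {
      pair$t[i] <- 0
      pair$p[i] <- 1
    } else {
      tt <- stats::t.test(d)
      pair$t[i] <- unname(tt$statistic)
      pair$p[i] <- tt$p.value
    }
  }
  if (is.null(m)) m <- nrow(pair)
  pair$significant <- hochberg_correct(pair$p, alpha = alpha, m = m)
  structure(list(runs = runs,
                 summary = data.frame(predictor = ids,
                                      mean = colMeans(runs),
                                      sd = apply(runs, 2, stats::sd)),
                 pairwise = pair, n_units = n, sample_size = k,
                 n_runs = n_runs, replace = replace),
            class = "es_comparison")
}

#' @export
print.es_comparison <- function(x, ...) {
  cat(sprintf("<es_comparison: %d predictors, %d runs of %d/%d units>\n",
              ncol(x$runs), x$n_runs, x$sample_size, x$n_units))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Ensemble improvement over a randomly selected model
#'
#' The headline improvement statistic: the ensemble's overall inverse
#' deviance minus the *median* of the individual models' overall inverse
#' deviances (the expected accuracy of picking a model at random),
#' expressed in percentage points of inverse deviance per validation
#' datapoint. Negative values mean the ensemble underperforms.
#'
#' @param ens An `es_accuracy` for the ensemble.
#' @param models List of `es_accuracy`, one per model (>= 2).
#' @return Improvement in percentage points, with the relative
#'   improvement (percent of the median-model accuracy) as attribute
#'   `"relative_pct"`.
#' @export
improvement_vs_random_model <- function(ens, models) {
  if (length(models) < 2) stop("need at least 2 models")
  med <- stats::median(vapply(models, function(a) a$overall, numeric(1)))
  out <- 100 * (ens$overall - med)
  attr(out, "relative_pct") <- 100 * (ens$overall - med) / med
  out
}

#' Cross-service proxy and bundle accuracies
#'
#' Scores each *other* service's ensemble as a proxy predictor of the
#' target service at the target's validation units, plus the "bundle":
#' the per-cell mean of the other services' normalized ensembles,
#' renormalized to the full 0-1 range, scored identically.
#'
#' @param ensembles Named list of `es_ensemble`, one per service (>= 2),
#'   all on one grid.
#' @param target Name of the target service in `ensembles`.
#' @param target_vs The target service's validation set.
#' @param mode,radius Extraction mode passed to [extract_predictions()].
#' @return Named list of `es_accuracy`: one per other service, one for
#'   `"bundle"`, and `"self"` for the target's own ensemble.
#' @export
proxy_and_bundle_accuracy <- function(ensembles, target, target_vs,
                                      mode = "polygon_sum", radius = NULL) {
  if (length(ensembles) < 2) stop("need at least 2 services")
  stopifnot(target %in% names(ensembles))
  others <- setdiff(names(ensembles), target)
  X_raw <- target_vs$observed

  score_layer <- function(layer, label) {
    y <- extract_predictions(layer$values, target_vs, mode = mode,
                             radius = radius, label = label)
    score_predictor(X_raw, y, label = label)
  }
  out <- lapply(others, function(s) score_layer(ensembles[[s]], s))
  names(out) <- others

  # bundle: unweighted per-cell mean of the other services' ensembles
  bundle_stack <- es_stack(lapply(ensembles[others], function(e) e$values))
  bundle <- renormalize_full_range(build_ensemble(bundle_stack, "mean"))
  out$bundle <- score_layer(bundle, "bundle")
  out$self <- score_layer(ensembles[[target]], "self")
  out
}
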