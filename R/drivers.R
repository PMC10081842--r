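#' Spatial-autocorrelation covariate
#'
#' For each point, the inverse-distance-weighted mean of the per-point
#' accuracies at all *other* points within `max_range` degrees
#' (Euclidean distance between centroids). Points with no neighbor in
#' range receive the global mean accuracy. When a neighbor is coincident
#' (distance 0), the coincident neighbors take all the weight.
#'
#' The functional form of the covariate is a package choice (the inverse
#' distance kernel is pluggable via `kernel`); what is fixed is that it
#' summarizes neighboring accuracy within a hard 5-degree range and is
#' entered first in the driver model.
#'
#' @param centroids Two-column matrix or data.frame of (lon, lat).
#' @param D_per_point Per-point inverse-deviance accuracies.
#' @param max_range Neighborhood radius in degrees (default 5).
#' @param kernel Weight as a function of distance (default `1/d`).
#' @return Numeric vector `Auto(x)`.
#' @export
auto_covariate <- function(centroids, D_per_point, max_range = 5,
                           kernel = function(d) 1 / d) {
  centroids <- as.matrix(centroids)
  n <- nrow(centroids)
  if (n < 2) stop("need at least 2 points")
  stopifnot(length(D_per_point) == n)
  dm <- as.matrix(stats::dist(centroids))
  gmean <- mean(D_per_point)
  out <- numeric(n)
  for (i in seq_len(n)) {
    d <- dm[i, -i]
    Dn <- D_per_point[-i]
    inr <- d <= max_range
    if (!any(inr)) {
      out[i] <- gmean
    } else if (any(d[inr] == 0)) {
      out[i] <- mean(Dn[inr][d[inr] == 0])
    } else {
      w <- kernel(d[inr])
      out[i] <- sum(w * Dn[inr]) / sum(w)
    }
  }
  out
}

#' Transform a driver metric toward normality
#'
#' Percentage-like metrics (Gini, % researchers, % GDP to R&D) are
#' arcsine-square-root transformed after scaling into \[0, 1\]; GDP per
#' capita is log10 transformed; HDI is used untransformed.
#'
#' @param values Numeric vector.
#' @param kind `"arcsine"`, `"log10"` or `"none"`.
#' @param scale100 For `arcsine`: divide by 100 first. `NULL` (default)
#'   auto-detects values in (1, 100].
#' @return Transformed vector.
#' @export
transform_metric <- function(values, kind = c("arcsine", "log10", "none"),
                             scale100 = NULL) {
  kind <- match.arg(kind)
  if (kind == "none") return(values)
  if (kind == "log10") {
    if (any(values <= 0)) stop("log10 transform requires positive values")
    return(log10(values))
  }
  if (is.null(scale100)) scale100 <- any(values > 1) && all(values <= 100)
  v <- if (scale100) values / 100 else values
  if (any(v < 0 | v > 1)) stop("arcsine transform requires values scalable into [0, 1]")
  asin(sqrt(v))
}

# default transform per conventional metric column name
default_metric_transform <- function(name) {
  switch(name,
         gdp_pc = "log10",
         hdi = "none",
         "arcsine")
}

#' Sequential-SS driver model for one metric
#'
#' Fits the linear model
#' `D(x) ~ b0 + b1 * Auto(x) + b2 * Metric(x) + e`
#' with type-I (sequential) sums of squares, the autocorrelation
#' covariate entered first so the metric is tested on what spatial
#' dependence leaves unexplained. The metric's one-sided p tests the
#' directional hypothesis that accuracy *increases* with the metric:
#' `p1 = p2/2` when the slope is positive, `1 - p2/2` otherwise. The
#' reported F value carries the sign of the slope ("mirrored") so the
#' direction is visible alongside the one-sided significance.
#'
#' @param D Per-point accuracy vector (n >= 10).
#' @param auto `Auto(x)` covariate (see [auto_covariate()]).
#' @param metric Transformed metric vector.
#' @param metric_name Label for the output.
#' @return An object of class `es_driver_test`: a data.frame of terms
#'   with `df`, `ss`, `F`, `F_signed`, `p_two_sided`, `p_one_sided`,
#'   `effect_sign`, plus the fitted coefficients as an attribute.
#' @export
driver_anova <- function(D, auto, metric, metric_name = "metric") {
  n <- length(D)
  stopifnot(length(auto) == n, length(metric) == n)
  if (n < 10) stop("need at least 10 points")
  if (stats::sd(auto) == 0 || stats::sd(metric) == 0) {
    stop("constant covariate")
  }
  fit <- stats::lm(D ~ auto + metric)
  if (any(is.na(stats::coef(fit)))) stop("rank-deficient design")
  an <- stats::anova(fit)  # sequential (type I) by construction
  slope <- unname(stats::coef(fit)["metric"])
  res <- data.frame(
    term = c("auto", metric_name, "residual"),
    df = an$Df,
    ss = an$`Sum Sq`,
    F = c(an$`F value`[1:2], NA),
    p_two_sided = c(an$`Pr(>F)`[1:2], NA)
  )
  sgn <- sign(slope)
  p2 <- res$p_two_sided[2]
  res$p_one_sided <- NA_real_
  res$p_one_sided[2] <- if (sgn >= 0) p2 / 2 else 1 - p2 / 2
  b1 <- unname(stats::coef(fit)["auto"])
  res$p_one_sided[1] <- if (b1 >= 0) res$p_two_sided[1] / 2 else 1 - res$p_two_sided[1] / 2
  res$F_signed <- res$F
  res$F_signed[2] <- sgn * res$F[2]
  res$F_signed[1] <- sign(b1) * res$F[1]
  structure(list(terms = res, coef = stats::coef(fit),
                 effect_sign = sgn, n = n, metric = metric_name),
            class = "es_driver_test")
}

#' @export
print.es_driver_test <- function(x, ...) {
  cat(sprintf("<es_driver_test (%s), n = %d>\n", x$metric, x$n))
  print(x$terms, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Two-factor interaction driver model
#'
#' `D(x) ~ b0 + b1 * Auto(x) + b2 * M1(x) + b3 * M2(x) + M1:M2 + e`,
#' with type-I (sequential) SS between the autocorrelation covariate and
#' the tested factors — Auto is entered first and absorbs its share —
#' and type-III (partial) SS among the two factors and their
#' interaction. The canonical use pairs GDP per capita with income
#' equality, income being better described by both mean and spread.
#'
#' @param D,auto As in [driver_anova()].
#' @param m1,m2 Transformed metric vectors.
#' @param names_ Labels for the two factors.
#' @return An `es_driver_test` whose term table has rows auto (type I),
#'   both mains and the interaction (type III), and residual.
#' @export
interaction_model <- function(D, auto, m1, m2, names_ = c("m1", "m2")) {
  n <- length(D)
  stopifnot(length(auto) == n, length(m1) == n, length(m2) == n)
  if (n < 10) stop("need at least 10 points")
  fit <- stats::lm(D ~ auto + m1 + m2 + m1:m2)
  if (any(is.na(stats::coef(fit)))) stop("rank-deficient design")
  seq_an <- stats::anova(fit)
  a3 <- car::Anova(fit, type = "III")
  rss <- a3["Residuals", "Sum Sq"]
  rdf <- a3["Residuals", "Df"]
  terms3 <- c("m1", "m2", "m1:m2")
  co <- stats::coef(fit)
  slopes <- c(auto = unname(co["auto"]), unname(co[c("m1", "m2", "m1:m2")]))
  res <- data.frame(
    term = c("auto", names_[1], names_[2],
             paste(names_, collapse = ":"), "residual"),
    df = c(seq_an["auto", "Df"], a3[terms3, "Df"], rdf),
    ss = c(seq_an["auto", "Sum Sq"], a3[terms3, "Sum Sq"], rss),
    F = c(seq_an["auto", "Sum Sq"] / seq_an["auto", "Df"] / (rss / rdf),
          a3[terms3, "F value"], NA),
    p_two_sided = NA_real_
  )
  res$p_two_sided[1] <- stats::pf(res$F[1], res$df[1], rdf, lower.tail = FALSE)
  res$p_two_sided[2:4] <- a3[terms3, "Pr(>F)"]
  sgns <- sign(slopes)
  res$p_one_sided <- NA_real_
  res$p_one_sided[1:4] <- ifelse(sgns >= 0, res$p_two_sided[1:4] / 2,
                                 1 - res$p_two_sided[1:4] / 2)
  res$F_signed <- res$F
  res$F_signed[1:4] <- sgns * res$F[1:4]
  structure(list(terms = res, coef = co, effect_sign = unname(sgns[-1]),
                 n = n, metric = paste(names_, collapse = " x ")),
            class = "es_driver_test")
}

#' Convergence bootstrap for standardized degrees of freedom
#'
#' Repeatedly subsamples `n_sample` points without replacement, fits the
#' sequential driver model, and accumulates the running mean of each
#' factor's sum of squares. Iteration stops once *every* factor's
#' running-mean SS has changed by no more than `tol` (relative; default
#' 0.05%) for `patience` consecutive iterations. F values are rebuilt
#' from the converged mean sums of squares with degrees of freedom
#' standardized at `n_sample`, equalizing power across validation sets
#' of very different sizes.
#'
#' @inheritParams driver_anova
#' @param centroids Point centroids (lon, lat), used to recompute the
#'   subsample's covariate when `auto` is not supplied.
#' @param n_sample Standard subsample size (default 178).
#' @param tol Relative change threshold (default 5e-4 = 0.05%).
#' @param patience Consecutive quiet iterations required (default 25).
#' @param max_iter Hard iteration cap; hitting it flags non-convergence.
#' @return An `es_driver_test` with the stabilized term table plus
#'   `iterations` and `converged` fields.
#' @export
convergence_bootstrap <- function(D, auto, metric, metric_name = "metric",
                                  n_sample = 178, tol = 5e-4, patience = 25,
                                  max_iter = 5000) {
  n <- length(D)
  if (n < n_sample) stop("need at least n_sample points")
  terms_n <- 3L  # auto, metric, residual
  ss_sum <- numeric(terms_n)
  sign_sum <- 0
  prev_mean <- NULL
  quiet <- 0L
  it <- 0L
  repeat {
    it <- it + 1L
    idx <- if (n == n_sample) seq_len(n) else sample.int(n, n_sample)
    ft <- driver_anova(D[idx], auto[idx], metric[idx], metric_name)
    ss_sum <- ss_sum + ft$terms$ss
    sign_sum <- sign_sum + ft$effect_sign
    cur_mean <- ss_sum / it
    if (!is.null(prev_mean)) {
      rel <- abs(cur_mean - prev_mean) / pmax(abs(prev_mean), .Machine$double.eps)
      quiet <- if (all(rel <= tol)) quiet + 1L else 0L
    }
    prev_mean <- cur_mean
    if (quiet >= patience || it >= max_iter) break
  }
  df <- c(1, 1, n_sample - 3)
  ms <- prev_mean / df
  Fv <- c(ms[1] / ms[3], ms[2] / ms[3], NA)
  p2 <- c(stats::pf(Fv[1], 1, df[3], lower.tail = FALSE),
          stats::pf(Fv[2], 1, df[3], lower.tail = FALSE), NA)
  sgn <- if (sign_sum >= 0) 1 else -1
  res <- data.frame(term = c("auto", metric_name, "residual"),
                    df = df, ss = prev_mean, F = Fv, p_two_sided = p2)
  res$p_one_sided <- NA_real_
  res$p_one_sided[2] <- if (sgn >= 0) p2[2] / 2 else 1 - p2[2] / 2
  res$F_signed <- res$F
  res$F_signed[2] <- sgn * res$F[2]
  structure(list(terms = res, effect_sign = sgn, n = n_sample,
                 metric = metric_name, iterations = it,
                 converged = quiet >= patience),
            class = "es_driver_test")
}

#' Full driver battery for one service
#'
#' Runs the five single-metric sequential models (GDP per capita, HDI,
#' Gini, % researchers, % GDP to R&D — or whatever metric columns are
#' supplied) plus the GDP-by-equality interaction model, yielding eight
#' tests per service (5 single metrics + 2 interaction mains + 1
#' interaction term), and applies the Hochberg step-up correction with
#' `m = 8` to the one-sided p values within the service.
#'
#' @param D Per-point accuracies.
#' @param centroids Matrix/data.frame of (lon, lat) per point.
#' @param metrics Data.frame of metric columns per point (>= 2 columns).
#' @param interaction_pair Two metric names for the interaction model
#'   (default `c("gdp_pc", "gini")`, falling back to the first two).
#' @param transforms Named character vector overriding the per-metric
#'   transform (`"arcsine"`, `"log10"`, `"none"`).
#' @param max_range Autocorrelation range in degrees.
#' @param alpha Family-wise level for the Hochberg flags.
#' @return Data.frame of class `es_driver_battery` with one row per test
#'   (metric, F_signed, p_one_sided, p_two_sided, effect_sign,
#'   corrected).
#' @export
driver_battery <- function(D, centroids, metrics,
                           interaction_pair = NULL, transforms = NULL,
                           max_range = 5, alpha = 0.05) {
  mnames <- names(metrics)
  if (length(mnames) < 2) stop("need at least 2 metric columns")
  if (is.null(interaction_pair)) {
    interaction_pair <- if (all(c("gdp_pc", "gini") %in% mnames)) {
      c("gdp_pc", "gini")
    } else {
      mnames[1:2]
    }
  }
  stopifnot(all(interaction_pair %in% mnames))
  auto <- auto_covariate(centroids, D, max_range = max_range)
  get_tx <- function(nm) {
    if (!is.null(transforms) && nm %in% names(transforms)) transforms[[nm]]
    else default_metric_transform(nm)
  }
  tmetrics <- lapply(mnames, function(nm) {
    transform_metric(metrics[[nm]], get_tx(nm))
  })
  names(tmetrics) <- mnames

  rows <- lapply(mnames, function(nm) {
    ft <- driver_anova(D, auto, tmetrics[[nm]], nm)
    r <- ft$terms[2, ]
    data.frame(test = nm, model = "single", F_signed = r$F_signed,
               p_one_sided = r$p_one_sided, p_two_sided = r$p_two_sided,
               effect_sign = ft$effect_sign, stringsAsFactors = FALSE)
  })
  im <- interaction_model(D, auto, tmetrics[[interaction_pair[1]]],
                          tmetrics[[interaction_pair[2]]],
                          names_ = interaction_pair)
  irows <- im$terms[2:4, ]
  rows <- c(rows, lapply(seq_len(3), function(i) {
    data.frame(test = irows$term[i], model = "interaction",
               F_signed = irows$F_signed[i],
               p_one_sided = irows$p_one_sided[i],
               p_two_sided = irows$p_two_sided[i],
               effect_sign = im$effect_sign[i], stringsAsFactors = FALSE)
  }))
  out <- do.call(rbind, rows)
  out$corrected <- hochberg_correct(out$p_one_sided, alpha = alpha,
                                    m = max(8L, nrow(out)))
  class(out) <- c("es_driver_battery", class(out))
  out
}
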