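test_that("Winsorising cuts match the linear-interpolation percentile oracle", {
  # independent oracle: manual linear interpolation between order stats
  pct_oracle <- function(x, p) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  p <- winsorise_fit(0:100)
  expect_equal(c(p$lower, p$upper), c(2.5, 97.5))
  p2 <- winsorise_fit(c(0, 10))
  expect_equal(c(p2$lower, p2$upper), c(0.25, 9.75))
  set.seed(5)
  for (n in c(7, 50, 301)) {
    x <- rlnorm(n)
    f <- winsorise_fit(x)
    expect_equal(f$lower, pct_oracle(x, 0.025), tolerance = 1e-12)
    expect_equal(f$upper, pct_oracle(x, 0.975), tolerance = 1e-12)
  }
  expect_error(winsorise_fit(rep(5, 10)), "degenerate")
  expect_error(winsorise_fit(numeric(0)), "degenerate")
})

test_that("Winsorising maps cuts to 0/1 and clamps beyond them", {
  p <- winsorise_fit(0:100)
  expect_equal(winsorise_apply(p$lower, p), 0)
  expect_equal(winsorise_apply(p$upper, p), 1)
  expect_equal(winsorise_apply(50, p), (50 - 2.5) / 95)
  expect_equal(winsorise_apply(-10, p), 0)
  expect_equal(winsorise_apply(1e6, p), 1)
  # no-data preserved on rasters
  r <- es_raster(matrix(c(1, NA, 3, 100), 2, 2))
  out <- winsorise_apply(r, p)
  expect_true(is.na(out$values[2, 1]))
  # roughly 2.5% of a continuous sample pins at each end
  set.seed(2)
  w <- winsorise(rnorm(4000))
  expect_true(all(w >= 0 & w <= 1))
  expect_gt(mean(w == 0), 0.015)
  expect_lt(mean(w == 0), 0.035)
})

test_that("ensemble statistics, counts and SEM follow their definitions", {
  g <- es_grid(n_rows = 1, n_cols = 3)
  st <- es_stack(list(
    a = es_raster(matrix(c(0.2, 0.2, 0.3), 1, 3), g),
    b = es_raster(matrix(c(0.4, NA, 0.5), 1, 3), g),
    c = es_raster(matrix(c(0.9, 0.6, 0.7), 1, 3), g)))
  e <- build_ensemble(st, "median")
  expect_equal(e$values$values[1, 1], 0.4)
  # no-data layer ignored: median of {0.2, 0.6} with even-n convention
  expect_equal(e$values$values[1, 2], 0.4)
  expect_equal(e$n_models$values[1, ], c(3, 2, 3))
  expect_equal(e$sem$values[1, 1], sd(c(0.2, 0.4, 0.9)) / sqrt(3),
               tolerance = 1e-12)
  # single-model cells get no-data SEM; all-agree cells get SEM 0
  st1 <- es_stack(list(a = es_raster(matrix(c(0.5, 0.5), 1, 2)),
                       b = es_raster(matrix(c(NA, 0.5), 1, 2))))
  e1 <- build_ensemble(st1, "median")
  expect_true(is.na(e1$sem$values[1, 1]))
  expect_equal(e1$sem$values[1, 2], 0)
  # K identical layers: ensemble equals each layer
  same <- es_stack(list(a = st$layers$a, b = st$layers$a, c = st$layers$a))
  expect_equal(build_ensemble(same, "median")$values$values,
               st$layers$a$values)
  expect_error(es_stack(list()))
})

test_that("median ensemble is invariant to layer order", {
  set.seed(12)
  g <- es_grid(n_rows = 5, n_cols = 5)
  layers <- lapply(1:4, function(i) {
    v <- matrix(runif(25), 5, 5); v[sample(25, 3)] <- NA
    es_raster(v, g)
  })
  names(layers) <- paste0("m", 1:4)
  e1 <- build_ensemble(es_stack(layers), "median")
  e2 <- build_ensemble(es_stack(rev(layers)), "median")
  expect_equal(e1$values$values, e2$values$values)
  expect_equal(e1$sem$values, e2$sem$values)
})

test_that("weighted mean is the plug-in cell statistic", {
  g <- es_grid(n_rows = 2, n_cols = 2)
  st <- es_stack(list(a = es_raster(matrix(0.2, 2, 2), g),
                      b = es_raster(matrix(0.8, 2, 2), g)))
  ew <- build_ensemble(st, "mean", weights = c(3, 1))
  expect_equal(ew$values$values, matrix(0.35, 2, 2))
  expect_equal(build_ensemble(st, "mean", weights = c(1, 1))$values$values,
               build_ensemble(st, "mean")$values$values)
  expect_error(build_ensemble(st, "median", weights = c(1, 1)), "mean")
})

test_that("full-range renormalization is an exact min-max rescale", {
  g <- es_grid(n_rows = 1, n_cols = 3)
  e <- build_ensemble(es_stack(list(
    a = es_raster(matrix(c(0.2, 0.4, 0.6), 1, 3), g),
    b = es_raster(matrix(c(0.2, 0.4, 0.6), 1, 3), g))), "median")
  rn <- renormalize_full_range(e)
  expect_equal(rn$values$values[1, ], c(0, 0.5, 1))
  expect_equal(range(rn$values$values), c(0, 1))
  # already spanning [0,1]: unchanged
  e01 <- build_ensemble(es_stack(list(
    a = es_raster(matrix(c(0, 0.5, 1), 1, 3), g))), "median")
  expect_equal(renormalize_full_range(e01)$values$values, e01$values$values)
  ecst <- build_ensemble(es_stack(list(a = es_raster(matrix(0.5, 1, 3), g))),
                         "median")
  expect_error(renormalize_full_range(ecst), "degenerate")
})

test_that("catchment aggregation sums or maxes data cells and conserves totals", {
  truth <- tiny_truth(21)
  whole <- gen_validation(truth, "polygon", 2, obs_noise_sd = 0, seed = 3)
  agg <- catchment_aggregate(truth, whole, "sum")
  expect_equal(sum(agg), sum(truth$values))
  # max mode picks the per-polygon maximum
  mx <- catchment_aggregate(truth, whole, "max")
  expect_equal(as.vector(mx),
               vapply(whole$cells, function(cs) {
                 max(as.vector(truth$values)[cs])
               }, numeric(1)))
  # no-data ignored; all-no-data polygons flagged missing
  v <- truth$values; v[unlist(whole$cells[1])] <- NA
  holed <- es_raster(v, truth$grid)
  agg2 <- catchment_aggregate(holed, whole, "sum")
  expect_true(is.na(agg2[1]))
  expect_equal(attr(agg2, "n_missing"), 1)
})
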