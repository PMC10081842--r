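test_that("prediction extraction matches direct lookup in all three modes", {
  truth <- tiny_truth(14)
  vs <- gen_validation(truth, "point", 15, obs_noise_sd = 0, seed = 2)
  y <- extract_predictions(truth, vs, "point_value")
  expect_equal(as.vector(y), vs$observed)
  # degenerate radius returns the containing cell
  y0 <- extract_predictions(truth, vs, "max_within_radius", radius = 0)
  expect_equal(as.vector(y0), as.vector(y))
  # polygon sums
  vp <- gen_validation(truth, "polygon", 4, obs_noise_sd = 0, seed = 6)
  ys <- extract_predictions(truth, vp, "polygon_sum")
  expect_equal(as.vector(ys), vp$observed)
  # missing units counted and NA-flagged
  v <- truth$values; v[unlist(vp$cells[2])] <- NA
  holed <- es_raster(v, truth$grid)
  yh <- extract_predictions(holed, vp, "polygon_sum")
  expect_true(is.na(yh[2]))
  expect_equal(attr(yh, "n_missing"), 1)
})

test_that("max-within-radius equals a brute-force scan of the neighborhood", {
  set.seed(44)
  g <- es_grid(cell_size = 0.1, n_rows = 20, n_cols = 20)
  v <- matrix(runif(400), 20, 20); v[sample(400, 40)] <- NA
  r <- es_raster(v, g)
  vs <- gen_validation(es_raster(matrix(runif(400), 20, 20), g),
                       "point", 25, obs_noise_sd = 0, seed = 9)
  cc <- cell_centers(g)
  for (radius in c(0.1, 0.25)) {
    y <- extract_predictions(r, vs, "max_within_radius", radius = radius)
    for (i in seq_len(nrow(vs))) {
      cell <- vs$cells[[i]]
      d <- sqrt((cc$lon - cc$lon[cell])^2 + (cc$lat - cc$lat[cell])^2)
      vals <- as.vector(v)[d <= radius + 1e-12]
      expect_equal(unname(y[i]), max(vals, na.rm = TRUE))
    }
  }
})

test_that("inverse deviance equals one minus mean absolute error", {
  expect_equal(deviance_accuracy(c(0.3, 0.7), c(0.3, 0.7))$overall, 1)
  expect_equal(deviance_accuracy(c(0, 0), c(1, 1))$overall, 0)
  a <- deviance_accuracy(c(0.5, 0.5), c(0.4, 0.7))
  expect_equal(a$overall, 0.85)
  expect_equal(a$per_point, c(0.9, 0.8))
  expect_equal(a$overall, mean(a$per_point))
  # brute-force loop oracle on random vectors
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(2:200, 1)
    X <- runif(n); Y <- runif(n)
    acc <- 0
    for (i in seq_len(n)) acc <- acc + abs(X[i] - Y[i])
    expect_equal(deviance_accuracy(X, Y)$overall, 1 - acc / n,
                 tolerance = 1e-14)
  }
  # permutation invariance
  X <- runif(30); Y <- runif(30); p <- sample(30)
  expect_equal(deviance_accuracy(X[p], Y[p])$overall,
               deviance_accuracy(X, Y)$overall)
  expect_error(deviance_accuracy(c(0.1, 0.2), c(0.1)), "length")
  expect_error(deviance_accuracy(c(0.1, 1.2), c(0.1, 0.2)), "normalized")
})

test_that("Hochberg step-up follows the textbook rule", {
  expect_equal(hochberg_correct(c(0.2, 0.4, 0.6)), rep(FALSE, 3))
  expect_equal(hochberg_correct(c(0.01, 0.02, 0.04, 0.2), m = 4),
               c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(hochberg_correct(rep(0, 5)), rep(TRUE, 5))
  # agrees with p.adjust when m equals the number of tests
  set.seed(3)
  for (rep in 1:25) {
    p <- runif(sample(2:8, 1))
    expect_equal(hochberg_correct(p, alpha = 0.05),
                 p.adjust(p, "hochberg") <= 0.05)
  }
  expect_error(hochberg_correct(c(0.5, 1.2)), "invalid")
  expect_error(hochberg_correct(runif(5), m = 3), "m must")
})

test_that("bootstrap comparison scores all predictors on identical resamples", {
  set.seed(10)
  X <- runif(120)
  good <- pmin(pmax(X + rnorm(120, sd = 0.02), 0), 1)
  bad <- pmin(pmax(X + rnorm(120, sd = 0.3), 0), 1)
  cmp <- {
    set.seed(1)
    bootstrap_compare(list(self = X, good = good, bad = bad), X,
                      n_runs = 200, sample_rule = "fixed", sample_size = 50)
  }
  # identical predictors tie exactly
  tie <- {
    set.seed(1)
    bootstrap_compare(list(a = good, b = good), X, n_runs = 100,
                      sample_rule = "fraction", sample_size = 0.10)
  }
  expect_equal(tie$pairwise$mean_diff, 0)
  expect_false(tie$pairwise$significant)
  # the truth itself dominates a noisy predictor
  sb <- cmp$pairwise[cmp$pairwise$a == "self" & cmp$pairwise$b == "bad", ]
  expect_gt(sb$mean_diff, 0)
  expect_true(sb$significant)
  # seeded reproducibility to machine precision
  cmp2 <- {
    set.seed(1)
    bootstrap_compare(list(self = X, good = good, bad = bad), X,
                      n_runs = 200, sample_rule = "fixed", sample_size = 50)
  }
  expect_identical(cmp$runs, cmp2$runs)
  expect_error(bootstrap_compare(list(a = X), X), "2 predictors")
})

test_that("improvement over a random model is in percentage points", {
  mk <- function(d) structure(list(overall = d), class = "es_accuracy")
  models <- lapply(c(0.60, 0.66, 0.70), mk)
  expect_equal(as.numeric(improvement_vs_random_model(mk(0.80), models)), 14)
  expect_equal(as.numeric(improvement_vs_random_model(mk(0.66), models)), 0)
  expect_lt(improvement_vs_random_model(mk(0.50), models), 0)
  expect_equal(attr(improvement_vs_random_model(mk(0.80), models),
                    "relative_pct"), 100 * 0.14 / 0.66)
  expect_error(improvement_vs_random_model(mk(0.8), models[1]), "2 models")
})

test_that("cross-service proxies score worse than self; bundles average", {
  truth1 <- tiny_truth(31, n = 24, clen = 5)
  truth2 <- es_raster(1 - truth1$values, truth1$grid)  # anti-correlated service
  mk_ens <- function(tr, seed) {
    st <- gen_model_outputs(tr, lapply(1:3, function(i) {
      model_spec(paste0("m", i), noise_sd = 0.05)
    }), seed = seed)
    renormalize_full_range(build_ensemble(normalize_stack(st), "median"))
  }
  ens <- list(s1 = mk_ens(truth1, 4), s2 = mk_ens(truth2, 9))
  vs <- gen_validation(truth1, "point", 60, obs_noise_sd = 0, seed = 5)
  out <- proxy_and_bundle_accuracy(ens, "s1", vs, mode = "point_value")
  expect_lt(out$s2$overall, out$self$overall)
  # self-proxy reproduces the direct accuracy computation
  direct <- score_predictor(vs$observed,
                            extract_predictions(ens$s1$values, vs, "point_value"))
  expect_equal(out$self$overall, direct$overall)
  # bundle of identical ensembles equals any member
  ens_same <- list(s1 = ens$s1, s2 = ens$s1, s3 = ens$s1)
  out2 <- proxy_and_bundle_accuracy(ens_same, "s1", vs, mode = "point_value")
  expect_equal(out2$bundle$overall, out2$s2$overall, tolerance = 1e-10)
})

test_that("per-unit SEM tracks per-unit ensemble error on heterogeneous worlds", {
  hits <- vapply(1:12, function(s) {
    r <- sim_sem_proxy_study(s)
    (r$rho > 0) && (r$p < 0.05)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
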