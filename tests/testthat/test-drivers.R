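test_that("autocorrelation covariate reduces to hand-computed IDW means", {
  # no neighbors in range: global mean everywhere
  far <- cbind(c(0, 10, 20), c(0, 0, 0))
  D <- c(0.2, 0.5, 0.8)
  expect_equal(auto_covariate(far, D, max_range = 5), rep(mean(D), 3))
  # coincident points take each other's accuracy
  co <- cbind(c(0, 0), c(0, 0))
  expect_equal(auto_covariate(co, c(0.3, 0.9)), c(0.9, 0.3))
  # collinear points at 0, 1, 2 degrees with D = (0, 1, 0):
  # middle sees (0, 0) at distance 1; ends see 1 at d=1 and 0 at d=2
  col3 <- cbind(c(0, 1, 2), c(0, 0, 0))
  a <- auto_covariate(col3, c(0, 1, 0))
  expect_equal(a[2], 0)
  expect_equal(a[1], (1 * 1 + 0.5 * 0) / 1.5)
  expect_equal(a[3], (1 * 1 + 0.5 * 0) / 1.5)
  expect_error(auto_covariate(cbind(1, 1), 0.5), "2 points")
})

test_that("metric transforms hit their closed forms and domains", {
  expect_equal(transform_metric(c(0, 1), "arcsine"), c(0, pi / 2))
  expect_equal(transform_metric(0.5, "arcsine"), pi / 4)
  expect_equal(transform_metric(1000, "log10"), 3)
  expect_equal(transform_metric(c(2, 7), "none"), c(2, 7))
  # percentage metrics auto-scale by 100
  expect_equal(transform_metric(50, "arcsine", scale100 = TRUE), pi / 4)
  expect_equal(transform_metric(c(25, 50, 75), "arcsine"),
               asin(sqrt(c(0.25, 0.5, 0.75))))
  expect_error(transform_metric(-1, "log10"), "positive")
  expect_error(transform_metric(c(0.5, 150), "arcsine"), "scalable")
})

test_that("sequential-SS model matches a normal-equations oracle exactly", {
  # independent oracle: RSS differences from explicit least squares
  seq_ss_oracle <- function(D, auto, metric) {
    rss <- function(Xm) {
      b <- solve(crossprod(Xm), crossprod(Xm, D))
      sum((D - Xm %*% b)^2)
    }
    n <- length(D)
    one <- matrix(1, n, 1)
    r0 <- rss(one)
    r1 <- rss(cbind(one, auto))
    r2 <- rss(cbind(one, auto, metric))
    ss <- c(r0 - r1, r1 - r2, r2)
    F <- c(ss[1] / (r2 / (n - 3)), ss[2] / (r2 / (n - 3)))
    list(ss = ss, F = F)
  }
  set.seed(30)
  D <- runif(30, 0.4, 1)
  auto <- runif(30)
  metric <- rnorm(30)
  ft <- driver_anova(D, auto, metric)
  or <- seq_ss_oracle(D, auto, metric)
  expect_equal(ft$terms$ss, or$ss, tolerance = 1e-10)
  expect_equal(ft$terms$F[1:2], or$F, tolerance = 1e-10)
  # a perfect predictor after Auto is overwhelmingly significant
  ft2 <- driver_anova(D, auto, D + 0.001 * rnorm(30))
  expect_gt(ft2$terms$F[2], 1000)
  expect_lt(ft2$terms$p_one_sided[2], 1e-10)
  # one-sided p flips with the slope sign
  ft3 <- driver_anova(D, auto, -D + 0.001 * rnorm(30))
  expect_gt(ft3$terms$p_one_sided[2], 0.99)
  expect_lt(ft3$terms$F_signed[2], 0)
  expect_error(driver_anova(D, rep(1, 30), metric), "constant")
})

test_that("interaction model: type I and III agree on orthogonal designs", {
  # balanced +-1 factorial replicated: all regressors mutually orthogonal
  base <- expand.grid(auto = c(-1, 1), m1 = c(-1, 1), m2 = c(-1, 1))
  X <- base[rep(seq_len(8), 4), ]
  set.seed(6)
  D <- 0.7 + 0.05 * X$m1 + 0.02 * X$m2 + rnorm(32, sd = 0.05)
  im <- interaction_model(D, X$auto, X$m1, X$m2)
  seq_fit <- anova(lm(D ~ auto + m1 + m2 + m1:m2, data = cbind(X, D = D)))
  expect_equal(im$terms$F[2:4],
               seq_fit[c("m1", "m2", "m1:m2"), "F value"], tolerance = 1e-10)
  expect_equal(im$terms$ss[2:4],
               seq_fit[c("m1", "m2", "m1:m2"), "Sum Sq"], tolerance = 1e-10)
})

test_that("a pure interaction effect lands on the interaction term", {
  set.seed(19)
  hits_int <- 0; hits_main <- 0
  for (rep in 1:10) {
    n <- 100
    m1 <- rnorm(n); m2 <- rnorm(n); auto <- rnorm(n)
    D <- 0.7 + 0.08 * m1 * m2 + rnorm(n, sd = 0.08)
    im <- interaction_model(D, auto, m1, m2)
    hits_int <- hits_int + (im$terms$p_two_sided[4] < 0.05)
    hits_main <- hits_main + (im$terms$p_two_sided[2] < 0.05)
  }
  expect_gte(hits_int, 8)
  expect_lte(hits_main, 3)
})

test_that("convergence bootstrap degenerates correctly at n = n_sample", {
  set.seed(40)
  n <- 40
  D <- runif(n, 0.5, 1); auto <- runif(n); metric <- rnorm(n)
  single <- driver_anova(D, auto, metric)
  cb <- convergence_bootstrap(D, auto, metric, n_sample = n, patience = 25)
  expect_true(cb$converged)
  expect_equal(cb$iterations, 26)  # patience quiet steps after the first
  expect_equal(cb$terms$F[1:2], single$terms$F[1:2], tolerance = 1e-12)
  # seeded determinism when genuinely subsampling
  r1 <- { set.seed(7); convergence_bootstrap(D, auto, metric, n_sample = 30) }
  r2 <- { set.seed(7); convergence_bootstrap(D, auto, metric, n_sample = 30) }
  expect_identical(r1$terms, r2$terms)
  expect_error(convergence_bootstrap(D, auto, metric, n_sample = 100),
               "n_sample")
})

test_that("the driver battery has 8 tests and flags only coupled metrics", {
  w <- sim_driver_study(101, coupling = 0)
  expect_s3_class(w$battery, "es_driver_battery")
  expect_equal(nrow(w$battery), 8)
  expect_equal(sum(w$battery$model == "single"), 5)
  expect_equal(sum(w$battery$model == "interaction"), 3)
  expect_setequal(w$battery$test[w$battery$model == "single"],
                  c("gdp_pc", "hdi", "gini", "researchers_pm", "rd_gdp_pct"))
  # coupled world: GDP flagged in most seeds, and the coupling raises
  # the marginal correlation substantially
  det <- vapply(1:8, function(s) {
    wc <- sim_driver_study(s + 500, coupling = -1.5)
    wc$battery$corrected[wc$battery$test == "gdp_pc" &
                           wc$battery$model == "single"]
  }, logical(1))
  expect_gte(mean(det), 0.5)
})
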