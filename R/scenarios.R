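#' Simulation study scenarios
#'
#' One-replicate builders for the package's three standing simulation
#' studies. Each is a pure function of its seed, so replicate sets are
#' reproducible and embarrassingly parallel. The parameter defaults ARE
#' the study conditions; see `vignette("ensemble-methods")` for why each
#' value was chosen.
#'
#' `sim_portfolio_study()` — the portfolio effect. A 64 x 64 world, nine
#' models that are truth plus idiosyncratic smooth bias fields
#' (weight 0.35) and i.i.d. noise (sd 0.15), 150 point validation units
#' (observation noise 0.02). With `shared_bias = TRUE` the idiosyncratic
#' terms are zeroed and all models carry one common bias field
#' (weight 0.8), the regime where averaging cannot cancel errors.
#' Returns the ensemble's improvement over the median model in
#' percentage points of inverse deviance.
#'
#' @param seed Integer replicate seed.
#' @param shared_bias Use the shared-bias (no-cancellation) regime.
#' @param statistic Ensemble statistic.
#' @return `sim_portfolio_study()`: list with `improvement_pp`,
#'   `ensemble_D`, `model_D` (vector), `win` (ensemble beats the median
#'   model).
#' @export
sim_portfolio_study <- function(seed, shared_bias = FALSE,
                                statistic = "median") {
  ws <- world_spec(64, 64, correlation_length = 8, seed = seed)
  truth <- gen_true_surface(ws)
  specs <- lapply(1:9, function(i) {
    if (shared_bias) {
      model_spec(paste0("m", i), bias_field_weight = 0,
                 shared_bias_weight = 0.8, noise_sd = 0)
    } else {
      model_spec(paste0("m", i), bias_field_weight = 0.35,
                 shared_bias_weight = 0, noise_sd = 0.15)
    }
  })
  st <- gen_model_outputs(truth, specs, seed = derive_seed(seed, 50))
  vs <- gen_validation(truth, "point", 150, obs_noise_sd = 0.02,
                       seed = derive_seed(seed, 60))
  nst <- normalize_stack(st)
  ens <- renormalize_full_range(build_ensemble(nst, statistic))
  X <- winsorise(vs$observed)
  accs <- lapply(names(nst$layers), function(id) {
    y <- winsorise(extract_predictions(nst$layers[[id]], vs, "point_value"))
    deviance_accuracy(X, y, id)
  })
  ey <- winsorise(extract_predictions(ens$values, vs, "point_value"))
  ens_acc <- deviance_accuracy(X, ey, "ensemble")
  imp <- improvement_vs_random_model(ens_acc, accs)
  list(improvement_pp = as.numeric(imp), ensemble_D = ens_acc$overall,
       model_D = vapply(accs, function(a) a$overall, numeric(1)),
       win = as.numeric(imp) > 0)
}

#' @description
#' `sim_sem_proxy_study()` — the SEM layer as an accuracy proxy. A
#' 48 x 48 world, seven models with heterogeneous noise (sd 0.02 to 0.6)
#' and 50% spatial coverage each, 500 point units: where noisier models
#' dominate a cell, both the between-model spread (SEM) and the ensemble
#' error are large, so per-unit SEM should rank-correlate with per-unit
#' absolute error.
#'
#' @return `sim_sem_proxy_study()`: list with Spearman `rho` and
#'   one-sided `p` for positive correlation between per-unit SEM and
#'   per-unit ensemble absolute error.
#' @rdname sim_portfolio_study
#' @export
sim_sem_proxy_study <- function(seed) {
  ws <- world_spec(48, 48, correlation_length = 6, seed = seed)
  truth <- gen_true_surface(ws)
  sds <- seq(0.02, 0.6, length.out = 7)
  specs <- lapply(1:7, function(i) {
    model_spec(paste0("m", i), noise_sd = sds[i], coverage_fraction = 0.5)
  })
  st <- gen_model_outputs(truth, specs, seed = derive_seed(seed, 70))
  nst <- normalize_stack(st)
  ens <- build_ensemble(nst, "median")
  vs <- gen_validation(truth, "point", 500, obs_noise_sd = 0,
                       seed = derive_seed(seed, 80))
  sem_u <- extract_predictions(ens$sem, vs, "point_value")
  y_u <- extract_predictions(ens$values, vs, "point_value")
  keep <- !is.na(sem_u) & !is.na(y_u)
  X <- winsorise(vs$observed[keep])
  Y <- winsorise(y_u[keep])
  ct <- suppressWarnings(stats::cor.test(sem_u[keep], abs(X - Y),
                                         method = "spearman",
                                         alternative = "greater"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(keep))
}

#' @description
#' `sim_driver_study()` — drivers of accuracy at country level. A
#' 64 x 64 world tiled into 178 countries (the standard driver sample
#' size), five models with noise sd 0.38, country-statistics validation
#' (observation noise 0.02 on the aggregated scale). With
#' `coupling = 0` the development metrics are independent of accuracy (a
#' null world for type-I calibration); `coupling = -1.5` scales model
#' noise down steeply with GDP-per-capita rank, making accuracy
#' genuinely increase with GDP (marginal correlation about 0.4, the
#' power regime).
#'
#' @param coupling Accuracy coupling passed to [country_spec()].
#' @return `sim_driver_study()`: list with the per-country accuracies
#'   `D`, `centroids`, `metrics`, the `battery` table from
#'   [driver_battery()], and `marginal_cor` (Pearson correlation of
#'   log10 GDP per capita with D).
#' @rdname sim_portfolio_study
#' @export
sim_driver_study <- function(seed, coupling = 0) {
  ws <- world_spec(64, 64, cell_size = 0.25, correlation_length = 6,
                   seed = seed)
  truth <- gen_true_surface(ws)
  cs <- country_spec(178, accuracy_coupling = coupling,
                     coupled_metric = "gdp_pc")
  countries <- gen_countries(cs, ws, seed = seed)
  specs <- lapply(1:5, function(i) model_spec(paste0("m", i), noise_sd = 0.38))
  st <- gen_model_outputs(truth, specs, seed = derive_seed(seed, 90),
                          noise_scale = countries$noise_scale)
  nst <- normalize_stack(st)
  ens <- renormalize_full_range(build_ensemble(nst, "median"))
  vs <- country_validation(truth, countries, obs_noise_sd = 0.02,
                           seed = derive_seed(seed, 95))
  X <- winsorise(vs$observed)
  Y <- winsorise(extract_predictions(ens$values, vs, "polygon_sum"))
  D <- 1 - abs(X - Y)
  metrics <- as.data.frame(vs)[c("gdp_pc", "hdi", "gini",
                                 "researchers_pm", "rd_gdp_pct")]
  bat <- driver_battery(D, cbind(vs$lon, vs$lat), metrics)
  list(D = D, centroids = cbind(lon = vs$lon, lat = vs$lat),
       metrics = metrics, battery = bat,
       marginal_cor = stats::cor(log10(metrics$gdp_pc), D))
}
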