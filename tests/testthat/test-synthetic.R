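test_that("true surface is deterministic, bounded, and rejects tiny grids", {
  ws <- world_spec(16, 16, correlation_length = 4, seed = 42)
  t1 <- gen_true_surface(ws)
  t2 <- gen_true_surface(ws)
  expect_identical(t1$values, t2$values)
  expect_true(all(t1$values >= 0 & t1$values <= 1))
  expect_equal(range(t1$values), c(0, 1))
  expect_error(world_spec(4, 16), "grid_rows")
})

test_that("correlation length controls spatial autocorrelation", {
  # no-smoothing case: cells i.i.d., lag-1 Moran's I near 0
  iid <- gen_true_surface(world_spec(24, 24, correlation_length = 1, seed = 9))
  expect_lt(abs(morans_i(iid$values, 1)), 0.1)
  # smoothed case: short-range correlation exceeds long-range
  sm <- gen_true_surface(world_spec(32, 32, correlation_length = 8, seed = 9))
  expect_gt(morans_i(sm$values, 1), morans_i(sm$values, 8))
  expect_gt(morans_i(sm$values, 1), 0.5)
})

test_that("model outputs follow the distortion model", {
  truth <- tiny_truth(3)
  # identity model reproduces truth exactly
  st <- gen_model_outputs(truth, list(model_spec("id")), seed = 5)
  expect_equal(st$layers$id$values, truth$values)
  # shared field cancels in differences between models
  sh <- gen_model_outputs(truth, list(
    model_spec("a", shared_bias_weight = 1),
    model_spec("b", shared_bias_weight = 1)), seed = 5)
  expect_equal(sh$layers$a$values, sh$layers$b$values)
  # duplicate ids rejected
  expect_error(gen_model_outputs(truth, list(model_spec("a"), model_spec("a")),
                                 seed = 1), "duplicate")
})

test_that("coverage_fraction drops about the right number of cells", {
  truth <- tiny_truth(4, n = 10)
  st <- gen_model_outputs(truth, list(model_spec("m", coverage_fraction = 0.5)),
                          seed = 11)
  n_data <- sum(!is.na(st$layers$m$values))
  expect_gte(n_data, qbinom(0.0005, 100, 0.5))
  expect_lte(n_data, qbinom(0.9995, 100, 0.5))
  # count layer bookkeeping
  st2 <- gen_model_outputs(truth, list(
    model_spec("a", coverage_fraction = 0.7),
    model_spec("b", coverage_fraction = 0.4)), seed = 3)
  manual <- (!is.na(st2$layers$a$values)) + (!is.na(st2$layers$b$values))
  expect_equal(st2$n_models$values, manual * 1.0)
})

test_that("validation units observe aggregated truth plus noise", {
  truth <- tiny_truth(6)
  # noiseless points return the exact cell value
  vp <- gen_validation(truth, "point", 20, obs_noise_sd = 0, seed = 2)
  expect_equal(vp$observed,
               as.vector(truth$values)[unlist(vp$cells)])
  # polygons tile the grid; noiseless sums conserve the grid total
  vg <- gen_validation(truth, "polygon", 4, obs_noise_sd = 0, seed = 2)
  expect_setequal(unlist(vg$cells), seq_len(16 * 16))
  expect_equal(sum(vg$observed), sum(truth$values))
  # Monte-Carlo: observation noise has the stated scale
  devs <- unlist(lapply(1:5, function(s) {
    v <- gen_validation(truth, "point", 100, obs_noise_sd = 0.1, seed = s)
    v$observed - v$observed_noiseless
  }))
  expect_lt(abs(sd(devs) - 0.1) / 0.1, 0.3)
  # catchments carry a pour point at the within-unit truth maximum
  vc <- gen_validation(truth, "catchment", 3, obs_noise_sd = 0, seed = 7)
  for (i in 1:3) {
    cells <- vc$cells[[i]]
    expect_equal(as.vector(truth$values)[vc$pour_cell[i]],
                 max(as.vector(truth$values)[cells]))
  }
  expect_error(gen_validation(truth, "point", 1000, seed = 1), "exceeds")
})

test_that("country tiling partitions the grid and metrics respect coupling", {
  ws <- world_spec(10, 10, seed = 5)
  cz <- gen_countries(country_spec(2), ws)
  expect_setequal(unlist(cz$units$cells), 1:100)
  expect_equal(sum(lengths(cz$units$cells)), 100)
  # null coupling: noise multiplier identically 1
  expect_true(all(cz$noise_scale$values == 1))
  # positive coupling: multiplier increases with the coupled metric
  cz2 <- gen_countries(country_spec(8, accuracy_coupling = 1), ws)
  m <- cz2$metrics$gdp_pc
  mult <- vapply(seq_len(8), function(k) {
    cz2$noise_scale$values[cz2$assignment$values == k][1]
  }, numeric(1))
  expect_equal(order(m), order(mult))
  expect_error(gen_countries(country_spec(200), ws), "exceeds")
})

test_that("coupled worlds raise model error where the metric is high", {
  ws <- world_spec(16, 16, seed = 1)
  truth <- gen_true_surface(ws)
  cors <- vapply(1:20, function(s) {
    cz <- gen_countries(country_spec(6, accuracy_coupling = 2), ws, seed = s)
    st <- gen_model_outputs(truth, list(model_spec("m", noise_sd = 0.2)),
                            seed = s + 100, noise_scale = cz$noise_scale)
    err <- abs(st$layers$m$values - truth$values)
    mean_err <- vapply(1:6, function(k) {
      mean(err[cz$assignment$values == k])
    }, numeric(1))
    cor(cz$metrics$gdp_pc, mean_err, method = "spearman")
  }, numeric(1))
  expect_gt(mean(cors), 0.5)
})

test_that("units survive a GeoJSON round trip", {
  truth <- tiny_truth(8)
  vs <- gen_validation(truth, "polygon", 5, obs_noise_sd = 0.1, seed = 3)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_units_geojson(vs, path, seed = 3)
  back <- read_units_geojson_table(path, truth$grid)
  expect_equal(back$observed, vs$observed)
  expect_equal(lapply(back$cells, sort), lapply(vs$cells, sort))
  pts <- gen_validation(truth, "point", 6, seed = 4)
  write_units_geojson(pts, path)
  back2 <- read_units_geojson_table(path, truth$grid)
  expect_equal(unlist(back2$cells), unlist(pts$cells))
})
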