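#!/usr/bin/env Rscript
# Stage 1 — simulate a synthetic service world with known ground truth.
#
# Builds one latent "true service" surface, five model outputs that
# distort it (idiosyncratic smooth bias fields + noise, one model with
# partial coverage), a country tiling with development metrics, and 178
# point validation units. Two models are exported on foreign grids
# (half and double resolution) so the harmonization stage has real work
# to do. All artifacts are plain text under results/world/.

library(esens)

out <- "results/world"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 42

ws <- world_spec(48, 48, cell_size = 0.25, correlation_length = 6, seed = seed)
truth <- gen_true_surface(ws)
write_asc(truth, file.path(out, "truth.asc"))

specs <- list(
  model_spec("m01", bias_gain = 1.0, bias_field_weight = 0.30, noise_sd = 0.15),
  model_spec("m02", bias_gain = 0.9, bias_field_weight = 0.35, noise_sd = 0.15),
  model_spec("m03", bias_gain = 1.1, bias_field_weight = 0.30, noise_sd = 0.20),
  model_spec("m04", bias_gain = 1.0, bias_field_weight = 0.25, noise_sd = 0.10,
             coverage_fraction = 0.7),
  model_spec("m05", bias_gain = 1.0, bias_field_weight = 0.40, noise_sd = 0.15)
)
stack <- gen_model_outputs(truth, specs, seed = seed + 1)

# export m01 upscaled (coarse, 0.5 deg) and m02 downscaled (fine,
# 0.125 deg): stage 2 must bring both back onto the 0.25 deg grid
write_asc(upscale_mean(stack$layers$m01, 2), file.path(out, "model_m01.asc"))
write_asc(downscale_bilinear(stack$layers$m02, 2), file.path(out, "model_m02.asc"))
for (id in c("m03", "m04", "m05")) {
  write_asc(stack$layers[[id]], file.path(out, sprintf("model_%s.asc", id)))
}

countries <- gen_countries(country_spec(12), ws, seed = seed)
write.csv(countries$metrics, file.path(out, "countries.csv"), row.names = FALSE)
write_asc(countries$assignment, file.path(out, "country_assignment.asc"))

vs <- gen_validation(truth, "point", 178, obs_noise_sd = 0.02, seed = seed + 2)
vs <- attach_country_metrics(vs, countries)
write_units_geojson(vs, file.path(out, "units.geojson"), seed = seed)

cat(sprintf("world: %d x %d cells at %.2f deg, correlation length %d cells\n",
            ws$grid_rows, ws$grid_cols, ws$cell_size, ws$correlation_length))
cat(sprintf("truth range [%.3f, %.3f]; %d models (m04 covers %.0f%% of cells)\n",
            min(truth$values), max(truth$values), length(specs),
            100 * mean(!is.na(stack$layers$m04$values))))
cat(sprintf("%d countries, %d point validation units written to %s/\n",
            nrow(countries$metrics), nrow(vs), out))
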