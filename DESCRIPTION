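Package: esens
Title: Ensembles of Ecosystem-Service Model Outputs with Accuracy Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds per-grid-cell ensembles (median or mean) from stacks of
    heterogeneous ecosystem-service model outputs and quantifies their
    accuracy and its spatial drivers. Harmonizes rasters of differing
    resolution onto a common grid with explicit no-data semantics,
    normalizes layers by a double-sided Winsorising protocol (2.5/97.5
    percentile cuts), computes committee ensembles with standard-error-of-
    the-mean uncertainty layers, scores predictions against point, polygon
    or catchment validation units with an inverse-of-deviance statistic,
    compares predictors by seeded bootstrap with pairwise t tests under
    Hochberg step-up correction, and tests country-level development
    metrics as drivers of per-point accuracy with sequential
    sum-of-squares ANOVA corrected for spatial autocorrelation. Includes a
    seeded synthetic-world generator (latent smooth service surfaces,
    biased noisy model outputs, validation units, country covariates) so
    the whole pipeline runs end-to-end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    car,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
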