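---
title: "Committee ensembles of ecosystem-service models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Committee ensembles of ecosystem-service models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esens)
```

Ecosystem-service (ES) models for the same service — water supply,
above-ground carbon, fuelwood, forage, recreation — disagree
substantially, and no single model is reliably the best everywhere. A
committee ensemble sidesteps model selection: normalize every model
output to a common scale, take the per-cell median, and carry an
explicit per-cell uncertainty layer. This package implements that
workflow end-to-end together with the statistics needed to defend it:
an accuracy score against independent reference data, bootstrap model
comparison with multiplicity control, and a regression framework for
asking *where* the ensemble is accurate. Because the real global model
outputs and validation datasets are large, external and partly
proprietary, the package ships a seeded synthetic-world generator with
the same statistical structure, so every claim the package makes is
testable against known ground truth.

## The model chain

**Harmonization.** Model rasters arrive on arbitrary grids. Layers finer
than the target grid are aggregated by block means with no-data cells
ignored (a coarse cell is no-data only when all members are); layers
coarser than the target are interpolated bilinearly from the four
nearest coarse cell centers, which preserves smooth transitions without
inventing sub-cell structure. Conventions the upstream tools leave
unstated had to be fixed here: cell-center registration with row 1 at
the north; half-open cell extents; bilinear no-data propagates to every
fine cell that a no-data center would influence with positive weight
(we prefer losing a fringe of cells to fabricating values at data
edges); beyond the outermost centers coordinates are clamped to the
nearest center. True zeros are data throughout — only the explicit
no-data mask is ignored by statistics.

**Normalization.** Each layer is rescaled by double-sided Winsorising:
the 2.5% and 97.5% percentiles of its data cells define 0 and 1, values
outside are clamped. This removes units (tonnes, m³, dollars) and tames
extremes without deleting them. Percentiles interpolate linearly
between order statistics (`stats::quantile` type 7); the choice is
stated because the 2.5% tail mass pinned at exactly 0/1 — which our
calibration tests check — depends on it. Validation vectors receive the
identical protocol before scoring, as do extracted prediction vectors,
so observed and predicted values always meet on the same \[0, 1\] scale.

**Ensembles.** The ensemble is the per-cell median (mean available;
per-model weights give the plug-in point for weighted variants) over
the models carrying data at that cell. Uncertainty is the standard
error of the mean, $\sigma(x)/\sqrt{n(x)}$, with the sample
(n−1) standard deviation; cells with one contributing model get
no-data SEM rather than a misleading 0. The value layer is then
min–max renormalized to span \[0, 1\]; the SEM layer is left on its
original scale, since rescaling an uncertainty by the value layer's
range would silently change its meaning.

**Accuracy.** For observed values $X(x)$ and predictions $Y(x)$ at $n$
validation units,

$$D^{\downarrow} = 1 - \frac{1}{n}\sum_x^n \lvert X(x) - Y(x)\rvert,$$

one minus the mean absolute deviation on the normalized scale; per-unit
accuracies are $1 - |X(x)-Y(x)|$. Spearman's ρ is reported alongside as
the purely rank-based alternative. Predictions are extracted per unit
as polygon sums (country statistics), point values (forest plots), or
the maximum within a radius of the unit's location (the flow-routing
correction for accumulated-flow layers, classically 0.041665°), clipped
to the unit's own polygon when one is supplied. Units missed by any
predictor are dropped listwise so every predictor faces identical
units.

**Comparison.** Predictors are compared within identical bootstrap
resamples — 1000 runs of a 10% fraction or a fixed 100 units,
subsampled *without* replacement (a with-replacement flag exists) —
with paired t tests on per-run accuracy differences and Hochberg's
step-up correction across the battery. The headline number is the
ensemble's overall $D^{\downarrow}$ minus the *median* of the models'
overall $D^{\downarrow}$ — the expected outcome of picking a model at
random — in percentage points (the relative version is attached as an
attribute). Two honesty notes are worth making explicit: bootstrap
replicates are not independent, so the paired t test's p values are
descriptive rather than exact; and the per-run mean of pairwise
differences is generally larger than the difference of averaged
accuracies.

**Drivers of accuracy.** Per-unit accuracy is regressed on one
development metric at a time,

$$D^{\downarrow}(x) \sim \beta_0 + \beta_1\,\mathrm{Auto}(x) + \beta_2\,\mathrm{Metric}(x) + \varepsilon,$$

with sequential (type-I) sums of squares and the spatial
autocorrelation covariate entered first. $\mathrm{Auto}(x)$ is the
inverse-distance-weighted mean of the accuracy at all *other* units
within 5°; the kernel is pluggable because no canonical form exists,
and units without neighbors in range receive the global mean.
Metrics are transformed toward normality first: GDP per capita
log10, percentage-like metrics (Gini, % researchers, % GDP to R&D)
arcsine-square-root after scaling into \[0, 1\], HDI untransformed.
Tests are one-sided for the directional hypothesis that accuracy
*increases* with development ($p_1 = p_2/2$ for a positive slope,
$1 - p_2/2$ otherwise), and the reported F carries the slope's sign so
direction stays visible. A two-factor interaction model (GDP ×
equality) uses type-I SS between Auto and the factors and type-III SS
among factors and interaction. The full battery per service is five
single-metric tests plus the two interaction mains and the interaction
term — eight tests — corrected with Hochberg's step-up at m = 8. For
validation sets much larger than the standard n = 178, a convergence
bootstrap repeatedly subsamples 178 units and accumulates running-mean
sums of squares until every factor's mean changes by ≤ 0.05% for 25
consecutive iterations ("every factor" is the stricter reading of an
ambiguous rule), then rebuilds F at the standardized degrees of
freedom.

## The synthetic worlds

The generator produces: a latent truth surface (white noise smoothed by
a Gaussian kernel of sd `correlation_length` cells, min–max rescaled to
\[0, 1\]; a correlation length of 1 means i.i.d. cells); model outputs
`bias_gain·truth + bias_field_weight·own_field +
shared_bias_weight·shared_field + noise` with per-cell Bernoulli
coverage; validation units (points; contiguous polygon tilings by
k-means on cell coordinates; catchments as polygons with a designated
pour-point cell at the within-unit truth maximum — real flow routing is
out of scope); and country tilings with metrics on realistic scales
(lognormal GDP per capita around $15k, HDI 0.40–0.95, Gini 25–60,
% researchers 0.02–1.2, R&D 0.1–4% of GDP). Observation noise is
additive Gaussian on the unit's aggregated scale — a stand-in, since
the error structure of real reference datasets is undocumented.

`accuracy_coupling` makes accuracy *genuinely* depend on one metric:
model noise is multiplied per country by
`max(0.05, 1 + coupling · u)` where `u` is the metric's percentile
rank. Positive coupling raises error with the metric; negative coupling
is the regime where wealthier countries get more accurate models. The
rank scale keeps the coupling monotone in the metric while independent
of its units (min–max scaling of lognormal GDP would compress most
countries near 0); magnitudes above 1 are meaningful because the
multiplier floors at 0.05.

What the worlds deliberately do **not** contain: reprojection between
datums (everything shares one geographic CRS), real flow routing,
spatially correlated observation error, and any resemblance to specific
real models or countries. Passing tests therefore demonstrate the
*statistical machinery* — cancellation of idiosyncratic errors,
calibration of the driver tests, SEM as an uncertainty proxy — not the
fidelity of any real-world ES map.

## The standing simulation studies

Three scenario functions freeze the package's study conditions; tests
and the acceptance script call them rather than re-specifying worlds.

**Portfolio effect** (`sim_portfolio_study`): 64 × 64 world, nine
models with idiosyncratic bias fields (weight 0.35) and noise sd 0.15,
150 point units. Idiosyncratic errors partially cancel in the median,
so the ensemble should beat the median model in nearly every world
(observed: every one of 200 seeds, mean improvement ≈ 7 pp). With one
shared bias field (weight 0.8) and idiosyncratic terms zeroed, all
models coincide after normalization and the improvement is exactly 0 —
shared assumptions are the regime averaging cannot fix.

**SEM as accuracy proxy** (`sim_sem_proxy_study`): seven models with
noise sd 0.02–0.6 and 50% coverage each, 500 point units. Which models
cover a cell varies, so the between-model spread (SEM) tracks the local
error level; the study checks a positive Spearman correlation between
per-unit SEM and per-unit ensemble absolute error. 500 units are used
because the population correlation is modest (ρ ≈ 0.2): at 250 units
the one-sided test had only ~85% power against its own premise, which
made the study report failures of power, not of the claim.

**Drivers** (`sim_driver_study`): 64 × 64 world tiled into 178
countries — the validation units *are* the countries, one observed
aggregate and one metric vector each, mirroring country-statistics
validation at the standard sample size. An earlier design with many
points sharing each country's metrics was rejected during development:
replicating a country-constant regressor across points is
pseudo-replication, and the one-sided tests ran visibly hot no matter
how the autocorrelation covariate was tuned. At country level the null
battery (coupling 0) shows a family-wise rejection rate of ~4% over
500 worlds. The power regime uses coupling −1.5 with model noise 0.38
and observation noise 0.02, calibrated so the true marginal correlation
between log-GDP and accuracy is ≈ 0.41; the corrected GDP test then
fires in ~94% of worlds. Two calibration dead ends are recorded for
the curious: coupling multipliers above 1 inflate a layer's Winsorise
range and destroy the correlation, and the correlation saturates near
0.40 because a single half-normal error draw per country carries
irreducible within-country variance.

## Numerical choices and degenerate inputs

* Percentile type 7; Winsorise cuts fitted on data cells only;
  degenerate layers (constant or < 2 distinct values) are an error, not
  silently passed through.
* Median with even n is the mean of the two central values.
* SEM at n = 1 is no-data; ensemble cells with n = 0 are no-data.
* Coincident points in the Auto covariate take all the weight (the
  1/d limit); a single isolated point is an error.
* Sequential SS comes from `anova(lm())`, verified in tests against an
  explicit normal-equations RSS-difference oracle to 1e-8; type-III SS
  comes from `car::Anova`.
* The convergence bootstrap with n equal to the sample size degenerates
  to the single fit and stops after the minimum 26 iterations.
* All generators are pure functions of (spec, seed); the pipeline fans
  a global seed out per stage as `(seed + 10007·stage) mod (2³¹−1)`,
  and a rerun with the same config reproduces byte-identical artifacts.

## Problem sizes

The shipped studies use 48–64 cell grids, 5–9 models, 150–500
validation units and 100–500 replicate worlds — sizes chosen so a full
replication runs in minutes on one core while keeping every Monte-Carlo
margin (win rates, FWER, power) far from its threshold. The machinery
is dimension-agnostic; nothing but memory and patience changes at
larger grids.

## Known limitations

* GeoTIFF/CRS handling is out of scope; rasters are exchanged as
  plain-text ASCII grids with an explicit no-data tag and a single
  implied geographic CRS.
* The bootstrap t tests inherit the dependence caveat above.
* The Auto covariate is one choice from a family; residual spatial
  dependence beyond what an IDW neighbor mean captures will leak into
  the metric tests.
* Catchment units are polygon approximations with a pour point; no
  hydrological routing.
* The weighted-ensemble family (PCA, correlation-coefficient,
  regression-to-the-median, leave-one-out log-likelihood) is not
  implemented; `build_ensemble(weights=)` is the extension hook.
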