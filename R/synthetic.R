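#' Synthetic-world specifications
#'
#' `world_spec()` fixes the grid and the smoothness of the latent "true
#' service" surface; `model_spec()` describes how one synthetic model
#' output distorts that truth; `country_spec()` controls the tiling of the
#' grid into countries and the coupling between a development metric and
#' local model noise.
#'
#' Distortion model: a synthetic model output is
#' `bias_gain * truth + bias_field_weight * own_field +
#'  shared_bias_weight * shared_field + noise`, where `own_field` is a
#' smooth surface unique to the model (idiosyncratic bias), `shared_field`
#' is one smooth surface common to every model in a call (shared
#' assumptions), and `noise` is i.i.d. Gaussian with sd `noise_sd`.
#' `coverage_fraction` of cells keep data; the rest become no-data.
#'
#' @param grid_rows,grid_cols Grid dimensions, each at least 8.
#' @param cell_size Cell size in degrees.
#' @param correlation_length Smoothness of latent surfaces, in cells
#'   (Gaussian kernel sd). Values `<= 1` mean no smoothing: i.i.d. cells.
#' @param seed Integer seed; identical spec + seed gives bit-identical
#'   output.
#' @param origin_lon,origin_lat Upper-left corner of the grid.
#' @return `world_spec()`: an object of class `es_world_spec`.
#' @export
world_spec <- function(grid_rows, grid_cols, cell_size = 0.1,
                       correlation_length = 6, seed = 1,
                       origin_lon = 0, origin_lat = 0) {
  stopifnot(grid_rows >= 8, grid_cols >= 8, correlation_length >= 1)
  structure(list(grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 cell_size = cell_size,
                 correlation_length = correlation_length,
                 seed = as.integer(seed),
                 origin_lon = origin_lon, origin_lat = origin_lat),
            class = "es_world_spec")
}

#' @param model_id Unique label of the model.
#' @param bias_gain Multiplicative distortion of truth.
#' @param bias_field_weight Weight on the model's own smooth bias field.
#' @param shared_bias_weight Weight on the bias field shared by all models.
#' @param noise_sd Additive Gaussian noise sd (>= 0).
#' @param coverage_fraction Fraction of cells with data, in (0, 1].
#' @return `model_spec()`: an object of class `es_model_spec`.
#' @rdname world_spec
#' @export
model_spec <- function(model_id, bias_gain = 1, bias_field_weight = 0,
                       shared_bias_weight = 0, noise_sd = 0,
                       coverage_fraction = 1) {
  stopifnot(noise_sd >= 0, coverage_fraction > 0, coverage_fraction <= 1)
  structure(list(model_id = as.character(model_id), bias_gain = bias_gain,
                 bias_field_weight = bias_field_weight,
                 shared_bias_weight = shared_bias_weight,
                 noise_sd = noise_sd,
                 coverage_fraction = coverage_fraction),
            class = "es_model_spec")
}

#' @param n_countries Number of contiguous country polygons (>= 2).
#' @param metric_names Development/equality metric columns to simulate.
#' @param accuracy_coupling Effect size linking the first metric to local
#'   model noise. Positive values scale noise *up* with the metric (model
#'   error increases where the metric is high); negative values scale it
#'   down, so accuracy increases with the metric; 0 gives a null world with
#'   metrics independent of accuracy.
#' @param coupled_metric Name of the metric driving the coupling (defaults
#'   to the first of `metric_names`).
#' @return `country_spec()`: an object of class `es_country_spec`.
#' @rdname world_spec
#' @export
country_spec <- function(n_countries,
                         metric_names = c("gdp_pc", "hdi", "gini",
                                          "researchers_pm", "rd_gdp_pct"),
                         accuracy_coupling = 0,
                         coupled_metric = metric_names[1]) {
  stopifnot(n_countries >= 2, length(metric_names) >= 1,
            coupled_metric %in% metric_names)
  structure(list(n_countries = as.integer(n_countries),
                 metric_names = metric_names,
                 accuracy_coupling = accuracy_coupling,
                 coupled_metric = coupled_metric),
            class = "es_country_spec")
}

# deterministic sub-seed fan-out; stays well below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 10007 * as.numeric(k)) %% 2147483647L)
}

# separable Gaussian smoothing with edge renormalization: rows of the
# banded operator are rescaled so constants are preserved at the borders
gaussian_smooth <- function(m, sd) {
  if (sd <= 0) return(m)
  half <- max(1L, ceiling(3 * sd))
  band_op <- function(n) {
    idx <- seq_len(n)
    w <- stats::dnorm(outer(idx, idx, `-`), sd = sd)
    w[abs(outer(idx, idx, `-`)) > half] <- 0
    w / rowSums(w)
  }
  band_op(nrow(m)) %*% m %*% t(band_op(ncol(m)))
}

# smooth standard-normal-ish field rescaled to [0, 1]
smooth_unit_field <- function(n_rows, n_cols, correlation_length, seed) {
  set.seed(seed)
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  if (correlation_length > 1) z <- gaussian_smooth(z, correlation_length)
  rng <- range(z)
  if (rng[1] == rng[2]) stop("degenerate field: constant surface")
  (z - rng[1]) / (rng[2] - rng[1])
}

#' Generate the latent true-service surface
#'
#' White noise smoothed by a Gaussian kernel of sd `correlation_length`
#' cells, then min-max rescaled to \[0, 1\]. With `correlation_length = 1`
#' no smoothing is applied and cells are i.i.d.
#'
#' @param spec A [world_spec()].
#' @return An [es_raster()] in \[0, 1\] carrying the spec as attribute
#'   `"world_spec"`.
#' @export
gen_true_surface <- function(spec) {
  stopifnot(inherits(spec, "es_world_spec"))
  vals <- smooth_unit_field(spec$grid_rows, spec$grid_cols,
                            spec$correlation_length,
                            derive_seed(spec$seed, 1))
  g <- es_grid(origin_lon = spec$origin_lon, origin_lat = spec$origin_lat,
               cell_size = spec$cell_size,
               n_rows = spec$grid_rows, n_cols = spec$grid_cols)
  r <- es_raster(vals, g)
  attr(r, "world_spec") <- spec
  r
}

#' Generate synthetic model outputs from a truth surface
#'
#' One raster per [model_spec()], each a biased, noisy, partially covered
#' view of the truth (see [world_spec()] for the distortion model). All
#' models within one call share a single shared-bias field, so ensembles
#' built from them inherit any bias carried by `shared_bias_weight` —
#' idiosyncratic bias fields and noise differ per model and can cancel.
#'
#' @param truth Truth raster from [gen_true_surface()].
#' @param specs List of [model_spec()] with distinct `model_id`s.
#' @param seed Integer seed.
#' @param noise_scale Optional raster of per-cell multipliers applied to
#'   every model's `noise_sd` (used to couple accuracy to country
#'   metrics, see [gen_countries()]).
#' @param field_correlation_length Smoothness of the bias fields, in
#'   cells; defaults to the truth's own correlation length.
#' @return An [es_stack()] keyed by model id, with per-cell model counts.
#' @export
gen_model_outputs <- function(truth, specs, seed, noise_scale = NULL,
                              field_correlation_length = NULL) {
  ids <- vapply(specs, function(s) s$model_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate model_id in specs")
  if (is.null(field_correlation_length)) {
    ws <- attr(truth, "world_spec")
    field_correlation_length <- if (is.null(ws)) 6 else ws$correlation_length
  }
  g <- truth$grid
  nr <- g$n_rows; nc <- g$n_cols
  if (!is.null(noise_scale)) {
    stopifnot(same_grid(noise_scale$grid, g))
    scale_m <- noise_scale$values
  } else {
    scale_m <- matrix(1, nr, nc)
  }
  shared <- smooth_unit_field(nr, nc, field_correlation_length,
                              derive_seed(seed, 2))
  layers <- vector("list", length(specs))
  names(layers) <- ids
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    own <- if (s$bias_field_weight != 0) {
      smooth_unit_field(nr, nc, field_correlation_length,
                        derive_seed(seed, 100 + i))
    } else {
      matrix(0, nr, nc)
    }
    set.seed(derive_seed(seed, 200 + i))
    noise <- matrix(stats::rnorm(nr * nc, sd = s$noise_sd), nr, nc) * scale_m
    v <- s$bias_gain * truth$values + s$bias_field_weight * own +
      s$shared_bias_weight * shared + noise
    if (s$coverage_fraction < 1) {
      set.seed(derive_seed(seed, 300 + i))
      drop <- matrix(stats::runif(nr * nc) >= s$coverage_fraction, nr, nc)
      v[drop] <- NA
    }
    v[is.na(truth$values)] <- NA
    layers[[i]] <- es_raster(v, g)
  }
  es_stack(layers)
}

#' Validation units
#'
#' Internal constructor for the unit table shared by validation sets and
#' country tilings: a data.frame with columns `unit_id`, `kind`, `lon`,
#' `lat` (centroid), `observed`, plus a list column `cells` of cell
#' indices into the grid (column-major) and, for catchments, the
#' designated pour-point cell.
#'
#' @noRd
es_units <- function(df, grid) {
  structure(df, grid = grid, class = c("es_units", class(df)))
}

#' @export
`[.es_units` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "grid") <- attr(x, "grid")
    class(out) <- class(x)
  }
  out
}

#' @export
print.es_units <- function(x, ...) {
  cat(sprintf("<es_units: %d %s units on %s>\n", nrow(x), x$kind[1],
              format(attr(x, "grid"))))
  print.data.frame(utils::head(as.data.frame(x)[setdiff(names(x), "cells")], 6))
  invisible(x)
}

# contiguous tiling of the grid cells into k clusters by k-means on
# cell-center coordinates; returns integer vector of cluster ids per cell
tile_grid <- function(grid, k, seed) {
  cc <- cell_centers(grid)
  if (k > nrow(cc)) stop("more tiles requested than grid cells")
  set.seed(seed)
  km <- suppressWarnings(stats::kmeans(cbind(cc$lon, cc$lat), centers = k,
                                       nstart = 1, iter.max = 500))
  km$cluster
}

#' Generate a validation set from the truth surface
#'
#' Each unit observes the truth aggregated over its footprint (point
#' units: the cell value; polygon and catchment units: the sum over their
#' cells) plus additive Gaussian measurement noise. Polygon and catchment
#' units tile the whole grid into contiguous non-overlapping pieces;
#' catchments additionally carry a pour-point cell (the cell of maximum
#' truth inside the unit), the target of max-mode extraction.
#'
#' @param truth Truth raster.
#' @param unit_kind One of `"point"`, `"polygon"`, `"catchment"`.
#' @param n_units Number of units (>= 2).
#' @param obs_noise_sd Observation noise sd on the aggregated scale.
#' @param seed Integer seed.
#' @return An `es_units` data.frame (see package docs) with `observed`
#'   values and centroids.
#' @export
gen_validation <- function(truth, unit_kind = c("point", "polygon", "catchment"),
                           n_units, obs_noise_sd = 0, seed = 1) {
  unit_kind <- match.arg(unit_kind)
  stopifnot(n_units >= 2, obs_noise_sd >= 0)
  g <- truth$grid
  cc <- cell_centers(g)
  n_cells <- nrow(cc)
  tv <- as.vector(truth$values)

  if (unit_kind == "point") {
    ok <- which(!is.na(tv))
    if (n_units > length(ok)) stop("n_units exceeds available data cells")
    set.seed(derive_seed(seed, 11))
    cells <- sort(sample(ok, n_units))
    cell_list <- as.list(cells)
    base_obs <- tv[cells]
    lon <- cc$lon[cells]; lat <- cc$lat[cells]
    pp <- cells
  } else {
    if (n_units > n_cells) stop("n_units exceeds available cells")
    tiles <- tile_grid(g, n_units, derive_seed(seed, 12))
    cell_list <- split(seq_len(n_cells), tiles)
    base_obs <- vapply(cell_list, function(cs) {
      vals <- tv[cs]
      if (all(is.na(vals))) NA_real_ else sum(vals, na.rm = TRUE)
    }, numeric(1))
    lon <- vapply(cell_list, function(cs) mean(cc$lon[cs]), numeric(1))
    lat <- vapply(cell_list, function(cs) mean(cc$lat[cs]), numeric(1))
    pp <- vapply(cell_list, function(cs) {
      vals <- tv[cs]
      if (all(is.na(vals))) NA_integer_ else cs[which.max(vals)]
    }, integer(1))
  }

  set.seed(derive_seed(seed, 13))
  noise <- stats::rnorm(n_units, sd = obs_noise_sd)
  df <- data.frame(unit_id = sprintf("u%03d", seq_len(n_units)),
                   kind = unit_kind, lon = lon, lat = lat,
                   observed = base_obs + noise,
                   observed_noiseless = base_obs,
                   stringsAsFactors = FALSE)
  df$cells <- unname(cell_list)
  if (unit_kind == "catchment") df$pour_cell <- pp
  es_units(df, g)
}

#' Generate country polygons with development metrics
#'
#' Tiles the grid into contiguous countries (k-means on cell
#' coordinates), draws per-country development/equality metrics on
#' realistic scales, and — when `accuracy_coupling != 0` — builds a
#' per-cell noise multiplier so that model noise genuinely depends on the
#' coupled metric (`multiplier = 1 + coupling * u`, where `u` is the
#' metric min-max scaled to \[0,1\], floored at 0.05). Feed the returned
#' `noise_scale` raster to [gen_model_outputs()] to realize the coupling.
#'
#' @param spec A [country_spec()].
#' @param world A [world_spec()] defining the grid.
#' @param seed Integer seed.
#' @return A list of class `es_countries`: `units` (an `es_units` table
#'   of country polygons with metric columns), `assignment` (raster of
#'   country ids per cell), `metrics` (per-country data.frame) and
#'   `noise_scale` (raster of noise multipliers; all 1 when coupling = 0).
#' @export
gen_countries <- function(spec, world, seed = world$seed) {
  stopifnot(inherits(spec, "es_country_spec"), inherits(world, "es_world_spec"))
  g <- es_grid(origin_lon = world$origin_lon, origin_lat = world$origin_lat,
               cell_size = world$cell_size,
               n_rows = world$grid_rows, n_cols = world$grid_cols)
  n_cells <- g$n_rows * g$n_cols
  if (spec$n_countries > n_cells) stop("n_countries exceeds grid cells")
  tiles <- tile_grid(g, spec$n_countries, derive_seed(seed, 21))
  cc <- cell_centers(g)
  cell_list <- split(seq_len(n_cells), tiles)

  set.seed(derive_seed(seed, 22))
  k <- spec$n_countries
  gen_metric <- function(name) {
    switch(name,
      gdp_pc = exp(stats::rnorm(k, mean = log(15000), sd = 1)),
      hdi = stats::runif(k, 0.40, 0.95),
      gini = stats::runif(k, 25, 60),
      researchers_pm = stats::runif(k, 0.02, 1.2),
      rd_gdp_pct = stats::runif(k, 0.1, 4),
      stats::runif(k)  # unrecognized metric names get a generic uniform
    )
  }
  metrics <- as.data.frame(lapply(spec$metric_names, gen_metric))
  names(metrics) <- spec$metric_names
  metrics <- cbind(country_id = sprintf("c%03d", seq_len(k)), metrics)

  mult <- rep(1, k)
  if (spec$accuracy_coupling != 0) {
    m <- metrics[[spec$coupled_metric]]
    # percentile rank keeps the coupling monotone in the metric but
    # insensitive to its scale (GDP is lognormal; min-max would compress
    # most countries near 0)
    u <- (rank(m, ties.method = "average") - 0.5) / length(m)
    mult <- pmax(0.05, 1 + spec$accuracy_coupling * u)
  }
  scale_v <- mult[tiles]

  df <- data.frame(unit_id = metrics$country_id, kind = "polygon",
                   lon = vapply(cell_list, function(cs) mean(cc$lon[cs]), numeric(1)),
                   lat = vapply(cell_list, function(cs) mean(cc$lat[cs]), numeric(1)),
                   observed = NA_real_, stringsAsFactors = FALSE)
  df$cells <- unname(cell_list)
  df <- cbind(df, metrics[-1])

  structure(list(units = es_units(df, g),
                 assignment = es_raster(matrix(tiles, g$n_rows, g$n_cols), g),
                 metrics = metrics,
                 noise_scale = es_raster(matrix(scale_v, g$n_rows, g$n_cols), g)),
            class = "es_countries")
}

#' Attach country metrics to validation units
#'
#' Assigns each unit to the country containing its centroid cell and
#' joins that country's metric columns onto the unit table.
#'
#' @param vs An `es_units` validation set.
#' @param countries An `es_countries` object on the same grid.
#' @return `vs` with added `country_id` and metric columns.
#' @export
attach_country_metrics <- function(vs, countries) {
  g <- attr(vs, "grid")
  stopifnot(same_grid(g, countries$assignment$grid))
  col <- pmin(pmax(ceiling((vs$lon - g$origin_lon) / g$cell_size), 1), g$n_cols)
  row <- pmin(pmax(ceiling((g$origin_lat - vs$lat) / g$cell_size), 1), g$n_rows)
  tile <- countries$assignment$values[cbind(row, col)]
  m <- countries$metrics[tile, , drop = FALSE]
  rownames(m) <- NULL
  out <- cbind(as.data.frame(vs), m)
  es_units(out, g)
}

#' Write validation units as GeoJSON
#'
#' Point units become Point features; polygon and catchment units become
#' MultiPolygon features (one square ring per member cell). Observed
#' values, metrics and the generator seed travel in the properties.
#'
#' @param vs An `es_units` table.
#' @param path Output path.
#' @param seed Optional seed recorded in the collection's properties.
#' @return `path`, invisibly.
#' @export
write_units_geojson <- function(vs, path, seed = NULL) {
  g <- attr(vs, "grid")
  cc <- cell_centers(g)
  h <- g$cell_size / 2
  features <- lapply(seq_len(nrow(vs)), function(i) {
    props <- as.list(as.data.frame(vs)[i, setdiff(names(vs), c("cells", "lon", "lat"))])
    if (vs$kind[i] == "point") {
      geom <- list(type = "Point", coordinates = c(vs$lon[i], vs$lat[i]))
    } else {
      cells <- vs$cells[[i]]
      rings <- lapply(cells, function(cl) {
        x <- cc$lon[cl]; y <- cc$lat[cl]
        list(list(c(x - h, y - h), c(x + h, y - h), c(x + h, y + h),
                  c(x - h, y + h), c(x - h, y - h)))
      })
      geom <- list(type = "MultiPolygon", coordinates = rings)
    }
    list(type = "Feature", geometry = geom, properties = props)
  })
  obj <- list(type = "FeatureCollection", features = features)
  if (!is.null(seed)) obj$properties <- list(seed = seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Use the country polygons themselves as validation units
#'
#' Country-level validation mirrors the national-statistics datasets
#' (fuelwood, forage, recreation): each country observes the truth
#' summed over its cells plus measurement noise, and carries its own
#' development metrics, so per-unit accuracy and metrics are matched
#' one-to-one with no within-country pseudo-replication.
#'
#' @param truth Truth raster on the countries' grid.
#' @param countries An `es_countries` object.
#' @param obs_noise_sd Observation noise sd on the aggregated scale.
#' @param seed Integer seed.
#' @return An `es_units` table of country polygons with `observed`
#'   filled and metric columns attached.
#' @export
country_validation <- function(truth, countries, obs_noise_sd = 0, seed = 1) {
  stopifnot(inherits(countries, "es_countries"),
            same_grid(truth$grid, countries$assignment$grid))
  vs <- countries$units
  tv <- as.vector(truth$values)
  base <- vapply(vs$cells, function(cs) {
    x <- tv[cs]
    if (all(is.na(x))) NA_real_ else sum(x, na.rm = TRUE)
  }, numeric(1))
  set.seed(derive_seed(seed, 31))
  vs$observed_noiseless <- base
  vs$observed <- base + stats::rnorm(length(base), sd = obs_noise_sd)
  vs$kind <- "polygon"
  vs
}
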