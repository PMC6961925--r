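#' Configuration for the synthetic gradient/community/survey generator
#'
#' Defaults emulate the study conditions of a tropical-montane ant survey:
#' nine 200 m elevation bands spanning 600-2400 m, a linear temperature
#' decline, a species pool whose range-size distribution puts more than half
#' of all species at three bands or fewer, cohesive range placement under a
#' temperature-weighted soft-low/hard-high boundary model, four transects
#' per band of which two carry 20 incidence sampling units and two carry 10,
#' and independent per-unit Bernoulli detection.
#'
#' @param n_bands Number of surveyed bands.
#' @param elev_low_m Lower edge of the lowest band (m).
#' @param band_width_m Band width (m).
#' @param temp_low_c Temperature weight at the lowest band (degrees C).
#' @param lapse_c Temperature drop per band (degrees C).
#' @param n_species Species pool size placed on the model domain. The
#'   default (185), with the default detection probability, yields around 157
#'   species detected inside the sampled window under the default placement
#'   model.
#' @param small_range_share Target share of the pool with ranges of at most
#'   `small_range_max` bands; the truncated-geometric size parameter is
#'   solved to hit it.
#' @param small_range_max Band-count threshold for a "small" range.
#' @param placement A [model_preset()] name or a [null_model_spec()].
#' @param extend_m Domain extension for preset placement models (m).
#' @param units_per_transect Incidence sampling units on each transect
#'   within a band (length = transects per band).
#' @param detect_p Per-unit, per-present-species detection probability.
#' @param rarefy_t Common unit count transect richness is rarefied to.
#' @param band_spacing_m Along-gradient distance between band origins, for
#'   synthetic transect coordinates.
#' @param transect_gap_m Range (min, max) of successive transect spacing
#'   within a band (m).
#' @param seed Integer seed used by [synth_dataset()].
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_bands = 9L, elev_low_m = 600, band_width_m = 200,
                         temp_low_c = 24, lapse_c = 1.5,
                         n_species = 185L, small_range_share = 0.55,
                         small_range_max = 3L,
                         placement = "model5", extend_m = 400,
                         units_per_transect = c(20L, 20L, 10L, 10L),
                         detect_p = 0.025, rarefy_t = 10L,
                         band_spacing_m = 2500, transect_gap_m = c(300, 1000),
                         seed = 1L) {
  stopifnot(n_bands >= 1L, n_species >= 1L,
            detect_p > 0, detect_p <= 1,
            small_range_share > 0, small_range_share < 1,
            all(units_per_transect >= 1L),
            rarefy_t >= 1L, rarefy_t <= min(units_per_transect))
  structure(
    list(n_bands = as.integer(n_bands), elev_low_m = elev_low_m,
         band_width_m = band_width_m, temp_low_c = temp_low_c,
         lapse_c = lapse_c, n_species = as.integer(n_species),
         small_range_share = small_range_share,
         small_range_max = as.integer(small_range_max),
         placement = placement, extend_m = extend_m,
         units_per_transect = as.integer(units_per_transect),
         detect_p = detect_p, rarefy_t = as.integer(rarefy_t),
         band_spacing_m = band_spacing_m, transect_gap_m = transect_gap_m,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Generate the banded temperature gradient
#'
#' @param config A [synth_config()].
#' @return A [band_grid()] with strictly decreasing weights when the lapse
#'   is positive.
#' @export
gen_gradient <- function(config) {
  n <- config$n_bands
  elev <- seq(config$elev_low_m, by = config$band_width_m, length.out = n)
  band_grid(elev, weights = config$temp_low_c - config$lapse_c * (0:(n - 1L)))
}

# solve the truncated-geometric parameter q (P(s) proportional to q^(s-1) on
# 1..n) so that P(size <= small_max) hits the target share
solve_size_param <- function(n, small_max, share) {
  if (small_max >= n) stop("small_range_max must be below n_bands")
  f <- function(lq) {
    q <- exp(lq)
    p <- q^(0:(n - 1L))
    sum(p[seq_len(small_max)]) / sum(p) - share
  }
  exp(stats::uniroot(f, c(-15, 15), tol = 1e-12)$root)
}

#' Range-size probabilities of the generator
#'
#' Truncated geometric on `1..n_bands`, parameter solved so the share of
#' sizes at or below `small_range_max` equals `small_range_share`.
#'
#' @param config A [synth_config()].
#' @return Numeric probability vector over sizes `1..n_bands`.
#' @export
size_distribution <- function(config) {
  q <- solve_size_param(config$n_bands, config$small_range_max,
                        config$small_range_share)
  p <- q^(0:(config$n_bands - 1L))
  p / sum(p)
}

#' Generate a synthetic community by randomized range placement
#'
#' Draws each species' range size from the truncated-geometric distribution
#' and its location from the configured placement model, on that model's
#' full domain. The returned raw occupancy is the *true* occupancy (before
#' any detection process): contiguous blocks under cohesive placement,
#' scattered band sets under scatter placement.
#'
#' @param config A [synth_config()].
#' @param grid The surveyed [band_grid()] (usually [gen_gradient()] output).
#' @return A `synth_community` list: `raw` ([incidence_matrix()] on the
#'   domain grid), `ranges` (interpolated [species_ranges()] on the domain),
#'   `sizes`, the placement `spec` and the surveyed `grid`.
#' @export
gen_community <- function(config, grid) {
  spec <- if (inherits(config$placement, "null_model_spec")) config$placement
          else model_preset(config$placement, grid, config$extend_m)
  dom <- domain_grid(spec, grid)
  n_dom <- n_bands(dom)
  probs <- size_distribution(config)
  sizes <- sample.int(config$n_bands, config$n_species, replace = TRUE,
                      prob = probs)
  sizes <- sort(sizes)
  cells <- matrix(0L, n_dom, config$n_species)
  if (spec$cohesion) {
    for (s in unique(sizes)) {
      js <- which(sizes == s)
      pl <- enumerate_placements(s, spec, grid)
      starts <- if (nrow(pl) == 1L) rep(pl$start, length(js))
                else sample(pl$start, length(js), replace = TRUE,
                            prob = pl$prob)
      for (i in seq_along(js))
        cells[starts[i]:(starts[i] + s - 1L), js[i]] <- 1L
    }
  } else {
    w <- if (spec$weighted) dom$weights else NULL
    for (j in seq_along(sizes))
      cells[sample.int(n_dom, sizes[j], prob = w), j] <- 1L
  }
  ids <- sprintf("sp%03d", seq_len(config$n_species))
  raw <- incidence_matrix(cells, dom, ids)
  structure(
    list(raw = raw, ranges = incidence_to_ranges(raw), sizes = sizes,
         spec = spec, grid = grid, config = config),
    class = "synth_community"
  )
}

#' Restrict a synthetic community to the surveyed window
#'
#' Drops domain bands outside the sampled window and any species whose true
#' occupancy misses the window entirely — the part of the pool a survey of
#' the window could never record.
#'
#' @param community A `synth_community`.
#' @return List with the window `grid`, the cropped true-occupancy `raw`
#'   matrix and its interpolated `ranges`.
#' @export
crop_to_window <- function(community) {
  dom <- community$raw$grid
  idx <- window_bands(dom)
  grid <- community$grid
  cells <- community$raw$cells[idx, , drop = FALSE]
  keep <- colSums(cells) >= 1L
  raw <- incidence_matrix(cells[, keep, drop = FALSE], grid,
                          community$raw$species_ids[keep])
  list(grid = grid, raw = raw, ranges = incidence_to_ranges(raw))
}

#' Simulate the transect survey over a synthetic community
#'
#' Each surveyed band holds `length(units_per_transect)` transects; every
#' sampling unit detects each species truly present in the band
#' independently with probability `detect_p`. Transect coordinates place
#' bands along one axis with 300-1000 m spacing between successive transects
#' inside a band, to give Moran's I something to measure. Observed richness
#' is rarefied to the common unit count `rarefy_t`.
#'
#' @param community A `synth_community` (see [gen_community()]).
#' @param config The [synth_config()] used to build it.
#' @return A `synth_survey` list: `transects` (data frame, one row per
#'   transect), `freqs` (per-transect [incidence_freqs()]),
#'   `observed_incidence` (band-level detected occupancy on the window
#'   grid; species detected nowhere are dropped).
#' @export
gen_survey <- function(community, config) {
  win <- crop_to_window(community)
  grid <- win$grid
  n_tr <- length(config$units_per_transect)
  if (config$detect_p == 0)
    warning("detection probability 0: survey will be empty")
  rows <- list()
  freqs <- list()
  det_band <- matrix(0L, n_bands(grid), ncol(win$raw$cells))
  tr_id <- 0L
  for (b in seq_len(n_bands(grid))) {
    present <- which(win$raw$cells[b, ] == 1L)
    x0 <- (b - 1L) * config$band_spacing_m
    xs <- x0 + cumsum(stats::runif(n_tr, config$transect_gap_m[1L],
                                   config$transect_gap_m[2L]))
    ys <- stats::runif(n_tr, 0, 200)
    for (tr in seq_len(n_tr)) {
      tr_id <- tr_id + 1L
      units <- config$units_per_transect[tr]
      Y <- if (length(present))
        stats::rbinom(length(present), units, config$detect_p)
      else integer(0)
      det <- Y >= 1L
      det_band[b, present[det]] <- 1L
      fr <- incidence_freqs(Y[det], T = units)
      freqs[[tr_id]] <- fr
      elev <- grid$elevations[b]
      rows[[tr_id]] <- data.frame(
        transect = sprintf("t%02d", tr_id),
        band_elevation_m = elev,
        n_units = units,
        observed_richness = length(fr$Y),
        rarefied_richness = if (length(fr$Y))
          rarefy_incidence(fr, config$rarefy_t) else 0,
        chao2 = if (length(fr$Y)) chao2(fr) else 0,
        mat_c = grid$weights[b],
        litter_volume = stats::rnorm(1, 8 + 0.0015 * elev, 1.5),
        understory_complexity = stats::rnorm(1, 1.5 + 2e-04 * elev, 0.4),
        x = xs[tr], y = ys[tr],
        stringsAsFactors = FALSE
      )
    }
  }
  transects <- do.call(rbind, rows)
  names(freqs) <- transects$transect
  keep <- colSums(det_band) >= 1L
  observed <- if (any(keep))
    incidence_matrix(det_band[, keep, drop = FALSE], grid,
                     win$raw$species_ids[keep])
  else NULL
  structure(
    list(transects = transects, freqs = freqs,
         observed_incidence = observed),
    class = "synth_survey"
  )
}

#' Generate a complete synthetic data set
#'
#' Seeds the generator from `config$seed` and chains [gen_gradient()],
#' [gen_community()] and [gen_survey()]; the result is fully reproducible
#' from the configuration alone.
#'
#' @param config A [synth_config()].
#' @return List with `grid`, `community` and `survey`.
#' @export
synth_dataset <- function(config = synth_config()) {
  set.seed(config$seed)
  grid <- gen_gradient(config)
  community <- gen_community(config, grid)
  survey <- gen_survey(community, config)
  list(grid = grid, community = community, survey = survey, config = config)
}

#' Simulate transect counts with a known temperature effect
#'
#' Convenience generator for regression-recovery experiments: transect
#' richness is drawn as Poisson with log-mean
#' `intercept + beta * standardized MAT`, with MAT taken from the band
#' gradient, ignoring the community/detection machinery.
#'
#' @param config A [synth_config()].
#' @param beta Slope on standardized mean annual temperature.
#' @param intercept Intercept on the log scale.
#' @return Data frame with `band_elevation_m`, `mat_c` and `richness`.
#' @export
gen_regression_data <- function(config, beta = 0.6, intercept = 2.5) {
  grid <- gen_gradient(config)
  n_tr <- length(config$units_per_transect)
  band <- rep(seq_len(n_bands(grid)), each = n_tr)
  mat <- grid$weights[band]
  mat_z <- as.numeric(scale(mat))
  data.frame(
    band_elevation_m = grid$elevations[band],
    mat_c = mat,
    richness = stats::rpois(length(band), exp(intercept + beta * mat_z))
  )
}

#' Write the synthetic tables to disk
#'
#' Emits `bands.csv` (band label and temperature), `ranges.csv` (the
#' interpolated elevational extents of the species the survey detected, in
#' the `species, min, max, range, mid, num_bands` dialect), `incidence.csv`
#' (raw detected band-level occupancy) and `transects.csv`. All files read
#' back through the package's own readers.
#'
#' @param dataset A [synth_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
emit_tables <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(bands = file.path(dir, "bands.csv"),
             ranges = file.path(dir, "ranges.csv"),
             incidence = file.path(dir, "incidence.csv"),
             transects = file.path(dir, "transects.csv"))
  write_band_table(dataset$grid, paths[["bands"]])
  obs <- dataset$survey$observed_incidence
  if (is.null(obs)) stop("survey detected no species; nothing to write")
  write_ranges(incidence_to_ranges(obs), paths[["ranges"]], dataset$grid)
  write_incidence(obs, paths[["incidence"]])
  utils::write.csv(dataset$survey$transects, paths[["transects"]],
                   row.names = FALSE, quote = FALSE)
  invisible(paths)
}
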