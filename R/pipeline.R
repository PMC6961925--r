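#' Pipeline configuration
#'
#' A flat configuration for the end-to-end analysis: either a synthetic-data
#' stage (via [synth_config()]) or paths to existing band/range/incidence/
#' transect CSVs, plus the null-model suite settings and seeds. Defaults
#' mirror the analysis this package reproduces: rarefaction to 10 units,
#' models 1-5 at 5000 replicates with model 1 as the designated null.
#'
#' @param synth A [synth_config()], or `NULL` when reading data from
#'   `paths`.
#' @param paths Named list/vector with elements `bands`, `ranges`,
#'   `incidence`, `transects` when `synth` is `NULL`.
#' @param models Model-preset names for the suite.
#' @param n_reps Replicates per null model.
#' @param ses_reps Replicates for the matrix-fill SES test.
#' @param n_perm Permutations for Moran's I.
#' @param rarefy_t Rarefaction target (units).
#' @param r2_baseline `"null"` or `"mean"` for the suite R-squared.
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Output directory for [run_pipeline()], or `NULL` to skip
#'   writing files.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synth = synth_config(), paths = NULL,
                            models = paste0("model", 1:5),
                            n_reps = 5000L, ses_reps = 999L, n_perm = 999L,
                            rarefy_t = 10L, r2_baseline = "null",
                            seed = 1L, out_dir = NULL) {
  if (is.null(synth) && is.null(paths))
    stop("either a synth config or input paths must be given")
  if (!is.null(paths)) {
    need <- c("bands", "ranges", "incidence", "transects")
    miss <- setdiff(need, names(paths))
    if (length(miss))
      stop("paths is missing: ", paste(miss, collapse = ", "))
  }
  structure(
    list(synth = synth, paths = paths, models = models,
         n_reps = as.integer(n_reps), ses_reps = as.integer(ses_reps),
         n_perm = as.integer(n_perm), rarefy_t = as.integer(rarefy_t),
         r2_baseline = match.arg(r2_baseline, c("null", "mean")),
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys are [pipeline_config()] arguments; a `synth` mapping holds
#' [synth_config()] arguments, and a `paths` mapping input file paths.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synth)) y$synth <- do.call(synth_config, y$synth)
  do.call(pipeline_config, y)
}

#' Validate analysis input files
#'
#' Checks the schema of each table, monotone and evenly spaced bands, range
#' sanity (min below max, elevations mapping onto the band grid) and
#' cross-file consistency (ranges and transects referencing bands that
#' exist). Findings are returned, not thrown.
#'
#' @param paths Named list/vector with any of `bands`, `ranges`,
#'   `incidence`, `transects`.
#' @return Data frame of findings (`file`, `rule`, `detail`); zero rows
#'   means everything passed.
#' @export
validate_inputs <- function(paths) {
  findings <- list()
  note <- function(file, rule, detail)
    findings[[length(findings) + 1L]] <<- data.frame(
      file = file, rule = rule, detail = detail, stringsAsFactors = FALSE)
  for (nm in names(paths)) {
    if (!file.exists(paths[[nm]]))
      note(nm, "exists", paste("file not found:", paths[[nm]]))
  }
  grid <- NULL
  if (!is.null(paths$bands) && file.exists(paths$bands)) {
    grid <- tryCatch(read_band_table(paths$bands), error = function(e) {
      note("bands", "schema", conditionMessage(e))
      NULL
    })
  }
  if (!is.null(paths$ranges) && file.exists(paths$ranges)) {
    tab <- tryCatch(utils::read.csv(paths$ranges), error = function(e) {
      note("ranges", "schema", conditionMessage(e))
      NULL
    })
    if (!is.null(tab)) {
      need <- c("species", "min", "max", "num_bands")
      miss <- setdiff(need, names(tab))
      if (length(miss))
        note("ranges", "schema",
             paste("missing columns:", paste(miss, collapse = ", ")))
      else {
        bad <- tab$species[tab$min > tab$max]
        if (length(bad))
          note("ranges", "min<=max",
               paste("min above max for:", paste(bad, collapse = ", ")))
        if (!is.null(grid)) {
          lo <- band_index(grid, tab$min)
          hi <- band_index(grid, tab$max)
          bad <- tab$species[is.na(lo) | is.na(hi)]
          if (length(bad))
            note("ranges", "bands-exist",
                 paste("elevation not on the band grid for:",
                       paste(bad, collapse = ", ")))
        }
      }
    }
  }
  if (!is.null(paths$transects) && file.exists(paths$transects)) {
    tab <- tryCatch(utils::read.csv(paths$transects),
                    error = function(e) {
                      note("transects", "schema", conditionMessage(e))
                      NULL
                    })
    if (!is.null(tab)) {
      if (!"band_elevation_m" %in% names(tab))
        note("transects", "schema", "missing column band_elevation_m")
      else if (!is.null(grid)) {
        bad <- unique(tab$band_elevation_m[
          is.na(band_index(grid, tab$band_elevation_m))])
        if (length(bad))
          note("transects", "bands-exist",
               paste("band(s) absent from band table:",
                     paste(bad, collapse = ", ")))
      }
    }
  }
  if (length(findings)) do.call(rbind, findings)
  else data.frame(file = character(), rule = character(),
                  detail = character(), stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Chains the stages in the order of the analysis it reproduces: data
#' (synthetic generation or ingest), per-transect rarefaction, regression
#' (Poisson GLMM comparison by AICc and Moran's I on richness and on
#' elevation-regression residuals), the geometric-constraints model suite,
#' and the matrix-fill SES test. Every stage seed derives from the master
#' seed, so a configuration reproduces all numbers exactly.
#'
#' @param config A [pipeline_config()].
#' @return An `elevrich_run` object with elements `data`, `regression`,
#'   `moran`, `suite`, `ses`, and the `config`. When `config$out_dir` is
#'   set, CSV outputs and a plain-text summary are written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  # --- data stage -----------------------------------------------------
  if (!is.null(config$synth)) {
    sc <- config$synth
    sc$seed <- seed
    ds <- synth_dataset(sc)
    grid <- ds$grid
    transects <- ds$survey$transects
    raw <- ds$survey$observed_incidence
    if (is.null(raw)) stop("stage data failed: survey detected no species")
    ranges <- incidence_to_ranges(raw)
    freqs <- ds$survey$freqs
  } else {
    bad <- validate_inputs(config$paths)
    if (nrow(bad))
      stop("stage data failed: ", nrow(bad), " validation finding(s); ",
           "run validate_inputs() for details")
    grid <- read_band_table(config$paths$bands)
    ranges <- read_ranges(config$paths$ranges, grid)
    raw <- read_incidence(config$paths$incidence, grid)
    transects <- utils::read.csv(config$paths$transects)
    freqs <- NULL
  }
  # --- rarefaction stage ----------------------------------------------
  if (!is.null(freqs) && !"rarefied_richness" %in% names(transects)) {
    transects$rarefied_richness <- vapply(
      freqs, rarefy_incidence, numeric(1L), t = config$rarefy_t)
  }
  if (!"rarefied_richness" %in% names(transects))
    stop("stage rarefaction failed: no incidence frequencies and no ",
         "rarefied_richness column")
  # --- regression stage -----------------------------------------------
  reg <- tryCatch({
    fits <- list(
      climate = fit_count_model(transects, "rarefied_richness", "mat_c",
                                random_intercept = "band_elevation_m"),
      climate_habitat = fit_count_model(
        transects, "rarefied_richness",
        c("mat_c", "litter_volume", "understory_complexity"),
        random_intercept = "band_elevation_m"),
      habitat = fit_count_model(
        transects, "rarefied_richness",
        c("litter_volume", "understory_complexity"),
        random_intercept = "band_elevation_m")
    )
    list(fits = fits, comparison = compare_models(fits))
  }, error = function(e)
    stop("stage regression failed: ", conditionMessage(e)))
  moran <- tryCatch({
    W <- build_spatial_weights(transects[, c("x", "y")], k = 4L)
    resid_fit <- stats::glm(rarefied_richness ~ band_elevation_m,
                            family = stats::poisson(), data = transects)
    list(
      richness = morans_i(transects$rarefied_richness, W,
                          n_perm = config$n_perm, seed = seed + 11L),
      residuals = morans_i(stats::residuals(resid_fit, type = "deviance"),
                           W, n_perm = config$n_perm, seed = seed + 12L)
    )
  }, error = function(e)
    stop("stage moran failed: ", conditionMessage(e)))
  # --- null-model stage -----------------------------------------------
  suite <- tryCatch(
    run_model_suite(ranges, grid, models = config$models,
                    n_reps = config$n_reps, seed = seed + 100L),
    error = function(e)
      stop("stage nullmodel failed: ", conditionMessage(e)))
  ses <- tryCatch(
    ses_fill(raw, n_reps = config$ses_reps, seed = seed + 200L),
    error = function(e)
      stop("stage ses failed: ", conditionMessage(e)))
  run <- structure(
    list(grid = grid, ranges = ranges, raw = raw, transects = transects,
         regression = reg, moran = moran, suite = suite, ses = ses,
         config = config, version = as.character(utils::packageVersion("elevrich"))),
    class = "elevrich_run"
  )
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

# write stage outputs: per-model band predictions, comparison table,
# regression comparison, Moran table, and a plain-text summary
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  preds <- do.call(rbind, lapply(names(run$suite$fits), function(m) {
    f <- run$suite$fits[[m]]
    idx <- window_bands(f$domain)
    data.frame(model = m, band_elevation_m = f$domain$elevations[idx],
               mean = f$mean[idx], q025 = f$q025[idx], q975 = f$q975[idx])
  }))
  utils::write.csv(preds, file.path(dir, "null_band_predictions.csv"),
                   row.names = FALSE)
  utils::write.csv(run$suite$table, file.path(dir, "model_comparison.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(run$regression$comparison),
                   file.path(dir, "regression_comparison.csv"),
                   row.names = FALSE)
  moran_tab <- data.frame(
    variable = c("rarefied richness", "residuals vs elevation"),
    I = c(run$moran$richness$I, run$moran$residuals$I),
    std_deviate = c(run$moran$richness$std_deviate,
                    run$moran$residuals$std_deviate),
    p_value = c(run$moran$richness$p_value, run$moran$residuals$p_value))
  utils::write.csv(moran_tab, file.path(dir, "morans_i.csv"),
                   row.names = FALSE)
  con <- file(file.path(dir, "summary.txt"), "w")
  on.exit(close(con))
  sink(con)
  print(run)
  sink()
  invisible(dir)
}

#' @export
print.elevrich_run <- function(x, ...) {
  cat(sprintf("elevrich pipeline run (seed %d, package %s)\n\n",
              x$config$seed, x$version))
  cat(sprintf("Data: %d bands, %d species, %d transects\n\n",
              n_bands(x$grid), nrow(x$ranges), nrow(x$transects)))
  cat("-- Range contiguity (matrix fill) --\n")
  print(x$ses)
  cat("\n-- Geometric-constraints model suite --\n")
  print(summary(x$suite))
  cat("\n-- Regression comparison (AICc) --\n")
  print(as.data.frame(
    within(x$regression$comparison, {
      AICc <- round(AICc, 2); deviance <- round(deviance, 2)
      delta_AICc <- round(delta_AICc, 2)
    })), row.names = FALSE)
  cat("\n-- Moran's I --\n")
  cat(sprintf("  richness:  I = %.2f, std deviate %.2f, p = %.4g\n",
              x$moran$richness$I, x$moran$richness$std_deviate,
              x$moran$richness$p_value))
  cat(sprintf("  residuals: I = %.2f, std deviate %.2f, p = %.4g\n",
              x$moran$residuals$I, x$moran$residuals$std_deviate,
              x$moran$residuals$p_value))
  invisible(x)
}
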