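#' Deviance-ratio R-squared between null-model predictions
#'
#' The fit of a candidate geometric-constraints model is summarized as
#' `R2 = 1 - dev(candidate) / dev(reference)`, where the deviance of a model
#' is the sum over sampled-window bands of squared differences between
#' observed richness and the model's mean predicted richness. The reference
#' is the designated null model (negative values mean the candidate is worse
#' than the null); alternatively the deviance about the observed mean can be
#' used as the baseline.
#'
#' @param observed Numeric observed richness per sampled-window band.
#' @param candidate,null `null_richness` objects (see [simulate_null()])
#'   whose sampled windows match `observed`.
#' @param baseline `"null"` (default) or `"mean"`.
#' @return The R-squared value (at most 1, possibly negative).
#' @export
model_r2 <- function(observed, candidate, null = NULL,
                     baseline = c("null", "mean")) {
  baseline <- match.arg(baseline)
  dev_c <- model_deviance(observed, candidate)
  dev_0 <- switch(baseline,
    null = {
      if (is.null(null)) stop("baseline = \"null\" needs a null model")
      model_deviance(observed, null)
    },
    mean = sum((observed - mean(observed))^2)
  )
  if (dev_0 <= 0) stop("reference deviance is zero")
  1 - dev_c / dev_0
}

# sum of squared residuals between observed window richness and the model's
# mean prediction
model_deviance <- function(observed, fit) {
  pred <- predict.null_richness(fit, "mean")
  if (length(pred) != length(observed))
    stop("observed richness and prediction window lengths differ")
  sum((observed - pred)^2)
}

#' Run and compare a suite of geometric-constraints models
#'
#' Simulates every requested model on the observed range-size frequency
#' distribution, then scores each against the observed per-band richness by
#' deviance-ratio R-squared, relative both to the designated null model
#' (by default model 1, the weighted range-scatter model) and to the
#' observed-mean baseline.
#'
#' @param ranges A [species_ranges()] table.
#' @param grid The surveyed [band_grid()].
#' @param observed Observed richness per sampled-window band; defaults to
#'   the interpolated band richness of `ranges`.
#' @param models Character vector of [model_preset()] names, or a named list
#'   of [null_model_spec()] objects. Must include the `null_model`.
#' @param n_reps Replicates per model.
#' @param seed Optional integer seed; per-model seeds are derived from it so
#'   a model's prediction does not depend on which other models run.
#' @param null_model Name of the designated null within `models`.
#' @param extend_m Domain extension passed to [model_preset()].
#' @return A `model_suite` object: a comparison `table` (model, deviance,
#'   `r2_vs_null`, `r2_vs_mean`) plus the per-model `null_richness` fits.
#' @export
run_model_suite <- function(ranges, grid, observed = NULL,
                            models = paste0("model", 1:5),
                            n_reps = 5000, seed = NULL,
                            null_model = "model1", extend_m = 400) {
  if (is.character(models)) {
    specs <- lapply(models, model_preset, grid = grid, extend_m = extend_m)
    names(specs) <- models
  } else {
    specs <- models
    if (is.null(names(specs)) || anyDuplicated(names(specs)))
      stop("a list of model specs must carry unique names")
  }
  if (!null_model %in% names(specs))
    stop("the designated null model (", null_model, ") is not in the suite")
  if (is.null(observed))
    observed <- band_richness(ranges, grid, window_only = TRUE)
  if (length(observed) != length(window_bands(grid)))
    stop("observed richness must cover the sampled window")
  fits <- vector("list", length(specs))
  names(fits) <- names(specs)
  for (i in seq_along(specs)) {
    s <- if (is.null(seed)) NULL else (seed + i * 1000L) %% .Machine$integer.max
    fits[[i]] <- simulate_null(ranges, specs[[i]], grid,
                               n_reps = n_reps, seed = s)
  }
  devs <- vapply(fits, function(f) model_deviance(observed, f), numeric(1L))
  dev_null <- devs[[null_model]]
  if (dev_null <= 0) stop("zero deviance for the designated null model")
  dev_mean <- sum((observed - mean(observed))^2)
  tab <- data.frame(
    model = names(specs),
    deviance = unname(devs),
    r2_vs_null = 1 - unname(devs) / dev_null,
    r2_vs_mean = 1 - unname(devs) / dev_mean,
    stringsAsFactors = FALSE
  )
  structure(
    list(table = tab, fits = fits, observed = observed,
         null_model = null_model, n_reps = n_reps, seed = seed),
    class = "model_suite"
  )
}

#' @export
print.model_suite <- function(x, digits = 2, ...) {
  cat(sprintf("Geometric-constraints model suite (%d replicates, null = %s)\n",
              x$n_reps, x$null_model))
  tab <- x$table
  tab$deviance <- round(tab$deviance, digits)
  tab$r2_vs_null <- round(tab$r2_vs_null, digits)
  tab$r2_vs_mean <- round(tab$r2_vs_mean, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.model_suite <- function(object, ...) {
  tab <- object$table
  cand <- tab[tab$model != object$null_model, , drop = FALSE]
  best <- cand$model[which.max(cand$r2_vs_null)]
  out <- list(table = tab, best_candidate = best,
              null_model = object$null_model,
              null_r2_vs_mean = tab$r2_vs_mean[tab$model == object$null_model])
  class(out) <- "summary.model_suite"
  out
}

#' @export
print.summary.model_suite <- function(x, ...) {
  cat(sprintf("Geometric-constraints model suite (null = %s)\n",
              x$null_model))
  tab <- x$table
  for (v in c("deviance", "r2_vs_null", "r2_vs_mean"))
    tab[[v]] <- round(tab[[v]], 2)
  print(tab, row.names = FALSE)
  cat(sprintf("Best candidate by R2 vs %s: %s\n", x$null_model,
              x$best_candidate))
  if (length(x$null_r2_vs_mean))
    cat(sprintf("Variance explained by the null model itself (vs mean): %.0f%%\n",
                100 * x$null_r2_vs_mean))
  invisible(x)
}

#' @export
plot.model_suite <- function(x, ...) {
  idx <- window_bands(x$fits[[1L]]$domain)
  el <- x$fits[[1L]]$domain$elevations[idx]
  cols <- grDevices::hcl.colors(length(x$fits), "Dark 3")
  ylim <- range(0, x$observed,
                vapply(x$fits, function(f) max(predict(f)), numeric(1L)))
  plot(el, x$observed, pch = 19, ylim = ylim,
       xlab = "Band elevation (m)", ylab = "Species richness", ...)
  for (i in seq_along(x$fits)) {
    f <- x$fits[[i]]
    graphics::lines(f$domain$elevations[window_bands(f$domain)],
                    predict(f), col = cols[i], lwd = 2)
  }
  graphics::legend("topright", legend = c("observed", names(x$fits)),
                   pch = c(19, rep(NA, length(x$fits))),
                   lty = c(NA, rep(1, length(x$fits))),
                   col = c("black", cols), bty = "n")
  invisible(x)
}
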