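#' Fit a Poisson count model (GLM or random-intercept GLMM)
#'
#' Fits `response ~ fixed` with a log link, adding a single random intercept
#' per level of `random_intercept` when given (via [lme4::glmer()], Laplace
#' approximation, maximum likelihood). Predictors are z-scored before
#' fitting by default so slope magnitudes are comparable across predictors.
#' Rarefied richness is a legitimate non-integer response here; the Poisson
#' likelihood is then a quasi-likelihood and the fit records a note instead
#' of rounding the data.
#'
#' @param data Data frame of transect-level observations.
#' @param response Name of the non-negative response column.
#' @param fixed Character vector of fixed-effect column names (possibly
#'   empty for an intercept-only model).
#' @param random_intercept Optional name of a grouping column (e.g. the
#'   elevation band) for a random intercept.
#' @param standardize Z-score the fixed-effect columns first.
#' @return A `count_fit` object: coefficient table, random-intercept
#'   variance, log-likelihood, number of parameters `k` (fixed effects plus
#'   variance components), `AICc`, and `deviance` (`-2 log L`).
#' @export
fit_count_model <- function(data, response, fixed = character(),
                            random_intercept = NULL, standardize = TRUE) {
  stopifnot(response %in% names(data))
  if (any(data[[response]] < 0)) stop("response must be non-negative")
  miss <- setdiff(c(fixed, random_intercept), names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  dat <- data
  if (standardize) for (v in fixed) dat[[v]] <- as.numeric(scale(dat[[v]]))
  rhs <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
  notes <- character()
  collect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    notes <<- c(notes, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  y <- dat[[response]]
  if (any(abs(y - round(y)) > 1e-8))
    notes <- c(notes, paste("non-integer response: Poisson likelihood is a",
                            "quasi-likelihood (log y! -> lgamma(y+1))"))
  if (is.null(random_intercept)) {
    fml <- stats::as.formula(paste(response, "~", rhs))
    fit <- collect(stats::glm(fml, family = stats::poisson(), data = dat))
    if (!fit$converged) notes <- c(notes, "IRLS did not converge")
    est <- stats::coef(summary(fit))[, 1:2, drop = FALSE]
    ranvar <- NA_real_
    ll <- poisson_loglik(y, stats::fitted(fit))
    k <- length(stats::coef(fit))
  } else {
    fml <- stats::as.formula(paste0(response, " ~ ", rhs,
                                    " + (1 | ", random_intercept, ")"))
    fit <- collect(lme4::glmer(fml, family = stats::poisson(), data = dat))
    msgs <- fit@optinfo$conv$lme4$messages
    if (!is.null(msgs)) notes <- c(notes, unlist(msgs))
    est <- collect(stats::coef(summary(fit))[, 1:2, drop = FALSE])
    ranvar <- collect(as.numeric(lme4::VarCorr(fit)[[random_intercept]]))
    ll <- glmer_loglik(fit, y)
    k <- attr(stats::logLik(fit), "df") # fixed effects + variance components
  }
  n <- nrow(dat)
  # one per-observation warning per non-integer value is noise; the single
  # quasi-likelihood note above already records the fact
  notes <- unique(notes[!grepl("non-integer x =", notes)])
  colnames(est) <- c("estimate", "std_error")
  structure(
    list(coefficients = est, random_variance = ranvar,
         loglik = ll, n = n, k = k,
         AICc = aicc(ll, k, n), AIC = -2 * ll + 2 * k,
         deviance = -2 * ll,
         response = response, fixed = fixed,
         random_intercept = random_intercept,
         standardized = standardize, notes = notes, fit = fit),
    class = "count_fit"
  )
}

x_log_y <- function(x, y) ifelse(x > 0, x * log(y), 0)

# Poisson log-likelihood with log(y!) continued as lgamma(y+1), so rarefied
# (non-integer) responses get a finite quasi-likelihood; identical to
# stats::logLik for integer responses
poisson_loglik <- function(y, mu) sum(x_log_y(y, mu) - mu - lgamma(y + 1))

# Laplace log-likelihood of a glmer fit rebuilt from its finite deviance
# components (-2 ll = ldL2 + u'u + sum of unit deviances - 2 ll_saturated);
# lme4's own logLik is -Inf for non-integer responses
glmer_loglik <- function(fit, y) {
  cmp <- fit@devcomp$cmp
  ll_sat <- sum(x_log_y(y, y) - y - lgamma(y + 1))
  -(cmp[["ldL2"]] + cmp[["ussq"]] + cmp[["drsum"]] - 2 * ll_sat) / 2
}

# small-sample corrected AIC
aicc <- function(loglik, k, n) {
  if (n <= k + 1) return(NA_real_)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' @export
print.count_fit <- function(x, ...) {
  cat(sprintf("Poisson %s: %s ~ %s\n",
              if (is.null(x$random_intercept)) "GLM" else
                sprintf("GLMM (random intercept: %s)", x$random_intercept),
              x$response,
              if (length(x$fixed)) paste(x$fixed, collapse = " + ") else "1"))
  print(round(x$coefficients, 3))
  if (!is.na(x$random_variance))
    cat(sprintf("Random-intercept variance: %.3g\n", x$random_variance))
  cat(sprintf("logLik %.2f, k %d, n %d, AICc %.2f, deviance %.2f\n",
              x$loglik, x$k, x$n, x$AICc, x$deviance))
  if (length(x$notes))
    cat("Notes:", paste(unique(x$notes), collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.count_fit <- function(object, ...) object$coefficients[, "estimate"]

#' @export
logLik.count_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' Compare fitted count models by AICc
#'
#' @param ... `count_fit` objects (optionally named), or a single list of
#'   them. All must share the response and sample size.
#' @return A data frame sorted by AICc with `delta_AICc`, of class
#'   `count_fit_comparison`.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1L]], "count_fit"))
    fits <- fits[[1L]]
  stopifnot(all(vapply(fits, inherits, logical(1L), "count_fit")))
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- paste0("fit", seq_along(fits))
  resp <- unique(vapply(fits, `[[`, character(1L), "response"))
  ns <- unique(vapply(fits, `[[`, numeric(1L), "n"))
  if (length(resp) > 1L) stop("models fit different responses")
  if (length(ns) > 1L) stop("models fit different sample sizes")
  tab <- data.frame(
    model = names(fits),
    predictors = vapply(fits, function(f)
      if (length(f$fixed)) paste(f$fixed, collapse = " + ") else "1",
      character(1L)),
    k = vapply(fits, `[[`, numeric(1L), "k"),
    AICc = vapply(fits, `[[`, numeric(1L), "AICc"),
    deviance = vapply(fits, `[[`, numeric(1L), "deviance"),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$AICc), , drop = FALSE]
  tab$delta_AICc <- tab$AICc - tab$AICc[1L]
  rownames(tab) <- NULL
  class(tab) <- c("count_fit_comparison", "data.frame")
  tab
}
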