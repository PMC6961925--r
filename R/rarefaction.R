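#' Incidence frequencies for one site
#'
#' Sample-based incidence data: `T` sampling units (e.g. Winkler samples) at
#' one transect and, per detected species, the number of units `Y` in which
#' it occurred.
#'
#' @param Y Integer vector of per-species incidence counts (1..T); species
#'   never detected are excluded.
#' @param T Number of sampling units.
#' @return An `incidence_freqs` object.
#' @export
incidence_freqs <- function(Y, T) {
  Y <- as.integer(Y)
  T <- as.integer(T)
  if (T < 1L) stop("T must be positive")
  if (any(Y < 1L) || any(Y > T))
    stop("incidence counts must lie in 1..T")
  structure(list(Y = Y, T = T), class = "incidence_freqs")
}

#' Sample-based incidence rarefaction
#'
#' Expected species richness in a random subset of `t` of the `T` sampling
#' units, computed from incidence frequencies:
#' `S(t) = S_obs - sum_i C(T - Y_i, t) / C(T, t)`.
#' This equals the exact average of observed richness over all `C(T, t)`
#' subsets of size `t`. No extrapolation beyond `T` is offered.
#'
#' @param freqs An [incidence_freqs()] object.
#' @param t Number of units to rarefy to, `1 <= t <= T`.
#' @return Expected richness at `t` units.
#' @examples
#' rarefy_incidence(incidence_freqs(c(3, 1), T = 3), t = 2) # 5/3
#' @export
rarefy_incidence <- function(freqs, t) {
  stopifnot(inherits(freqs, "incidence_freqs"))
  t <- as.integer(t)
  if (t < 1L || t > freqs$T)
    stop("t must lie in 1..T (no extrapolation)")
  s_obs <- length(freqs$Y)
  if (s_obs == 0L) return(0)
  # lchoose(a, t) is -Inf for a < t, so absent terms vanish
  miss <- exp(lchoose(freqs$T - freqs$Y, t) - lchoose(freqs$T, t))
  s_obs - sum(miss)
}

#' Chao2 incidence-based richness estimator
#'
#' Nonparametric lower-bound estimate of total richness from the numbers of
#' uniques (`q1`, species in exactly one unit) and duplicates (`q2`, species
#' in exactly two):
#' `S_obs + ((T-1)/T) * q1^2 / (2 q2)` when `q2 > 0`, and the bias-corrected
#' `S_obs + ((T-1)/T) * q1 (q1 - 1) / 2` otherwise. Never below `S_obs`.
#'
#' @param freqs An [incidence_freqs()] object with `T >= 2`.
#' @return The Chao2 richness estimate.
#' @export
chao2 <- function(freqs) {
  stopifnot(inherits(freqs, "incidence_freqs"))
  if (freqs$T < 2L) stop("Chao2 needs at least two sampling units")
  s_obs <- length(freqs$Y)
  q1 <- sum(freqs$Y == 1L)
  q2 <- sum(freqs$Y == 2L)
  corr <- (freqs$T - 1) / freqs$T
  if (q2 > 0L) s_obs + corr * q1^2 / (2 * q2)
  else s_obs + corr * q1 * (q1 - 1) / 2
}
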