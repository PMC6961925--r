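#' Domain boundary policy
#'
#' Each edge of the model domain is either *hard* (no randomized range may
#' cross it; candidate placements that would are excluded) or *soft*
#' (niche-truncation: infeasible placements are shifted to the nearest
#' feasible position, piling probability mass onto the edge placement).
#'
#' @param low,high `"hard"` or `"soft"`.
#' @return A `boundary_policy` object.
#' @export
boundary_policy <- function(low = c("hard", "soft"), high = c("hard", "soft")) {
  low <- match.arg(low)
  high <- match.arg(high)
  structure(list(low = low, high = high), class = "boundary_policy")
}

#' Geometric-constraints null model configuration
#'
#' Bundles the four switches that define a random-placement null model:
#' range cohesion (contiguous blocks) versus scatter (independent bands),
#' uniform versus environmentally weighted midpoint selection, the boundary
#' policy at each domain edge, and the domain extent in metres.
#'
#' @param cohesion Logical; `TRUE` places each species as one contiguous
#'   block of bands, `FALSE` scatters its occupied bands independently.
#' @param weighted Logical; `TRUE` weights midpoint (or, for scatter, band)
#'   selection probabilities by the grid's environmental weights.
#' @param boundary A [boundary_policy()]. Ignored for scatter models.
#' @param domain_low_m,domain_high_m Domain edges in metres (see
#'   [extend_grid()]); `NULL` means the sampled grid's own edges.
#' @param label Optional display name.
#' @return A `null_model_spec` object.
#' @seealso [model_preset()] for the standard model 1-5 configurations.
#' @export
null_model_spec <- function(cohesion = TRUE, weighted = TRUE,
                            boundary = boundary_policy(),
                            domain_low_m = NULL, domain_high_m = NULL,
                            label = NULL) {
  stopifnot(is.logical(cohesion), length(cohesion) == 1L,
            is.logical(weighted), length(weighted) == 1L,
            inherits(boundary, "boundary_policy"))
  if (is.null(label))
    label <- paste0(if (cohesion) "cohesion" else "scatter",
                    if (weighted) "+weighted" else "+uniform",
                    "/", boundary$low, "-", boundary$high)
  structure(
    list(cohesion = cohesion, weighted = weighted, boundary = boundary,
         domain_low_m = domain_low_m, domain_high_m = domain_high_m,
         label = label),
    class = "null_model_spec"
  )
}

#' @export
print.null_model_spec <- function(x, ...) {
  cat("Null model:", x$label, "\n")
  cat(sprintf("  placement: %s, %s midpoint weighting\n",
              if (x$cohesion) "range cohesion" else "range scatter",
              if (x$weighted) "environmental" else "uniform"))
  if (x$cohesion)
    cat(sprintf("  boundaries: low %s, high %s\n",
                x$boundary$low, x$boundary$high))
  if (!is.null(x$domain_low_m))
    cat(sprintf("  domain: %g-%g m\n", x$domain_low_m, x$domain_high_m))
  invisible(x)
}

#' Standard null-model presets
#'
#' The five model variants compared in the analysis, on a surveyed gradient
#' with edges 600-2400 m and an extended domain reaching 200-2800 m:
#' \describe{
#'   \item{model1}{range scatter, temperature weighted, extended domain —
#'     the biologically motivated null for the suite comparison.}
#'   \item{model2}{range cohesion, weighted, hard boundaries at both ends.}
#'   \item{model3}{cohesion, weighted, soft (niche-truncation) boundaries at
#'     both ends.}
#'   \item{model4}{cohesion, weighted, soft low / hard high boundary.}
#'   \item{model5}{model 4 with the upper domain edge pulled back to the
#'     surveyed upper edge.}
#' }
#'
#' @param which One of `"model1"`..`"model5"`.
#' @param grid The surveyed [band_grid()]; fixes the domain edges.
#' @param extend_m How far beyond each surveyed edge the extended domain
#'   reaches, in metres (default 400, i.e. two 200 m bands).
#' @return A [null_model_spec()].
#' @export
model_preset <- function(which = c("model1", "model2", "model3", "model4",
                                   "model5"),
                         grid, extend_m = 400) {
  which <- match.arg(which)
  lo <- grid$elevations[1L]
  hi <- grid$elevations[n_bands(grid)] + grid$band_width
  ext_lo <- lo - extend_m
  ext_hi <- hi + extend_m
  switch(which,
    model1 = null_model_spec(cohesion = FALSE, weighted = TRUE,
                             domain_low_m = ext_lo, domain_high_m = ext_hi,
                             label = "model1"),
    model2 = null_model_spec(TRUE, TRUE, boundary_policy("hard", "hard"),
                             ext_lo, ext_hi, label = "model2"),
    model3 = null_model_spec(TRUE, TRUE, boundary_policy("soft", "soft"),
                             ext_lo, ext_hi, label = "model3"),
    model4 = null_model_spec(TRUE, TRUE, boundary_policy("soft", "hard"),
                             ext_lo, ext_hi, label = "model4"),
    model5 = null_model_spec(TRUE, TRUE, boundary_policy("soft", "hard"),
                             ext_lo, hi, label = "model5")
  )
}

# realize the model's domain grid (possibly the sampled grid itself)
domain_grid <- function(spec, grid) {
  if (is.null(spec$domain_low_m)) return(grid)
  lo <- grid$elevations[1L]
  hi <- grid$elevations[n_bands(grid)] + grid$band_width
  if (spec$domain_low_m == lo && spec$domain_high_m == hi) return(grid)
  extend_grid(grid, spec$domain_low_m, spec$domain_high_m)
}

# index of the candidate-midpoint band inside a block of `size` starting at
# `start`: the central band, the lower of the two central bands for even sizes
mid_offset <- function(size) (size - 1L) %/% 2L

#' Enumerate feasible range placements and their probabilities
#'
#' For a cohesive range of `range_size` bands on the model's domain, lists
#' every distinct placement (identified by its start band) with its selection
#' probability. Candidate midpoints are the domain's own bands; a candidate
#' whose block would cross a hard edge is excluded (with renormalization),
#' one crossing a soft edge is clamped to the nearest feasible start so its
#' mass accumulates on the edge placement. With `weighted = TRUE` each
#' candidate midpoint is weighted by the environmental value of its band
#' before clamping and normalization.
#'
#' @param range_size Range size in bands.
#' @param spec A [null_model_spec()] (must have `cohesion = TRUE`).
#' @param grid The surveyed [band_grid()]; the domain is derived via the
#'   spec's domain edges.
#' @return A data frame with columns `start` and `prob` (summing to 1), with
#'   the domain grid attached as attribute `domain`.
#' @examples
#' g <- band_grid(seq(600, 1400, 200))
#' enumerate_placements(3, null_model_spec(weighted = FALSE), g)
#' @export
enumerate_placements <- function(range_size, spec, grid) {
  if (!spec$cohesion)
    stop("placement enumeration is defined for cohesive (contiguous) models")
  dom <- domain_grid(spec, grid)
  n <- n_bands(dom)
  s <- as.integer(range_size)
  if (s < 1L || s > n)
    stop("range size must be between 1 and the domain length (", n, ")")
  off <- mid_offset(s)
  cand_mid <- seq_len(n)
  start <- cand_mid - off
  end <- start + s - 1L
  w <- if (spec$weighted) dom$weights[cand_mid] else rep(1, n)
  keep <- rep(TRUE, n)
  low_over <- start < 1L
  high_over <- end > n
  if (spec$boundary$low == "hard") keep[low_over] <- FALSE
  else start[low_over] <- 1L
  if (spec$boundary$high == "hard") keep[high_over] <- FALSE
  else start[high_over] <- n - s + 1L
  start <- start[keep]
  w <- w[keep]
  if (!length(start) || sum(w) <= 0)
    stop("no feasible placement for range size ", s,
         " under the given boundary policy/weights")
  prob <- tapply(w, start, sum) / sum(w)
  out <- data.frame(start = as.integer(names(prob)),
                    prob = as.numeric(prob))
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "domain") <- dom
  attr(out, "range_size") <- s
  out
}

#' Per-band coverage probabilities implied by a placement enumeration
#'
#' @param placements Result of [enumerate_placements()].
#' @return Numeric vector over domain bands: the probability that a randomly
#'   placed range of the enumerated size covers each band.
#' @export
placement_coverage <- function(placements) {
  dom <- attr(placements, "domain")
  s <- attr(placements, "range_size")
  n <- n_bands(dom)
  cov <- numeric(n)
  for (i in seq_len(nrow(placements))) {
    b <- placements$start[i]:(placements$start[i] + s - 1L)
    cov[b] <- cov[b] + placements$prob[i]
  }
  cov
}

#' Draw one randomized range placement
#'
#' Cohesive specs draw a contiguous block of exactly `range_size` bands with
#' the probabilities of [enumerate_placements()]; scatter specs draw
#' `range_size` distinct bands without replacement with per-band
#' probabilities proportional to the weights (uniform when unweighted).
#'
#' @inheritParams enumerate_placements
#' @return Integer vector of occupied domain band indices.
#' @export
draw_placement <- function(range_size, spec, grid) {
  dom <- domain_grid(spec, grid)
  n <- n_bands(dom)
  s <- as.integer(range_size)
  if (spec$cohesion) {
    pl <- enumerate_placements(s, spec, grid)
    start <- if (nrow(pl) == 1L) pl$start else
      sample(pl$start, 1L, prob = pl$prob)
    return(start:(start + s - 1L))
  }
  w <- if (spec$weighted) dom$weights else rep(1, n)
  if (s > sum(w > 0))
    stop("scatter draw needs at least range_size bands with positive weight")
  sort(sample.int(n, s, prob = w))
}
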