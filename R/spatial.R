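#' k-nearest-neighbour spatial weights
#'
#' Builds a symmetrized k-nearest-neighbour graph over site coordinates and
#' (by default) row-standardizes the weights, the usual scheme for Moran's I
#' on irregular survey designs.
#'
#' @param coords Two-column matrix or data frame of site coordinates.
#' @param k Number of nearest neighbours per site.
#' @param row_standardize Divide each row by its sum (sites with neighbours).
#' @return A `spatial_weights` object with the `n x n` weight matrix `W`.
#' @export
build_spatial_weights <- function(coords, k = 4L, row_standardize = TRUE) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < k + 1L) stop("need at least k + 1 sites")
  d <- as.matrix(stats::dist(coords))
  if (any(d[upper.tri(d)] == 0)) stop("duplicate coordinates")
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[-1L][seq_len(k)]
    A[i, nb] <- 1
  }
  A <- pmax(A, t(A)) # symmetrize: i~j if either nominates the other
  if (row_standardize) {
    rs <- rowSums(A)
    A[rs > 0, ] <- A[rs > 0, , drop = FALSE] / rs[rs > 0]
  }
  structure(list(W = A, n = n, k = as.integer(k),
                 row_standardized = row_standardize),
            class = "spatial_weights")
}

#' Moran's I with permutation inference
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z` the centred
#' values and `S0` the total weight; the null expectation is `-1/(n-1)`.
#' Significance comes from random relabelings of the values over sites; the
#' permutation mean and standard deviation also give a standard deviate for
#' the observed statistic.
#'
#' @param values Numeric vector, one value per site (not all equal).
#' @param W A [build_spatial_weights()] object (or a plain weight matrix).
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @param alternative `"greater"` (positive autocorrelation, default),
#'   `"less"`, or `"two.sided"`.
#' @return A `morans_i` object with `I`, `expectation`, `std_deviate`,
#'   `p_value`, and the permutation draws.
#' @export
morans_i <- function(values, W, n_perm = 999L, seed = NULL,
                     alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (inherits(W, "spatial_weights")) W <- W$W
  n <- length(values)
  if (n < 3L) stop("need at least three sites")
  if (nrow(W) != n || ncol(W) != n)
    stop("weight matrix does not match the number of sites")
  if (stats::var(values) == 0) stop("values have zero variance")
  if (!is.null(seed)) set.seed(seed)
  stat <- function(x) {
    z <- x - mean(x)
    (n / sum(W)) * sum(W * outer(z, z)) / sum(z^2)
  }
  I <- stat(values)
  perm <- vapply(seq_len(n_perm), function(i) stat(sample(values)),
                 numeric(1L))
  p <- switch(alternative,
    greater = (1 + sum(perm >= I)) / (n_perm + 1),
    less = (1 + sum(perm <= I)) / (n_perm + 1),
    two.sided = min(1, 2 * min((1 + sum(perm >= I)) / (n_perm + 1),
                               (1 + sum(perm <= I)) / (n_perm + 1)))
  )
  structure(
    list(I = I, expectation = -1 / (n - 1),
         perm_mean = mean(perm), perm_sd = stats::sd(perm),
         std_deviate = (I - mean(perm)) / stats::sd(perm),
         p_value = p, n_perm = n_perm, alternative = alternative,
         perm = perm),
    class = "morans_i"
  )
}

#' @export
print.morans_i <- function(x, ...) {
  cat("Moran's I permutation test\n")
  cat(sprintf("  I = %.3f (null expectation %.3f)\n", x$I, x$expectation))
  cat(sprintf("  standard deviate %.2f, p = %.4g (%s, %d permutations)\n",
              x$std_deviate, x$p_value, x$alternative, x$n_perm))
  invisible(x)
}
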