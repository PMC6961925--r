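#' Ordered elevation-band grid
#'
#' A `band_grid` describes the discretisation of an elevational gradient into
#' contiguous bands of constant width, together with a per-band environmental
#' weight (typically mean annual temperature) and the sub-range of bands that
#' was actually surveyed (the *sampled window*). Bands are labelled by the
#' elevation of their lower edge; all geometry downstream is done on band
#' indices `1..n`, so the labelling convention carries no analytic weight.
#'
#' @param elevations Numeric vector of band labels in metres, strictly
#'   increasing with constant spacing.
#' @param weights Non-negative numeric vector of per-band environmental
#'   weights, same length as `elevations`. Defaults to uniform weights.
#' @param band_width Band width in metres. Inferred from the spacing of
#'   `elevations` when two or more bands are given.
#' @param window Integer vector `c(first, last)` of band indices delimiting
#'   the sampled window. Defaults to the whole grid.
#'
#' @return An object of class `band_grid`: a list with elements
#'   `elevations`, `band_width`, `weights` and `window`.
#' @examples
#' band_grid(seq(600, 2200, by = 200), weights = seq(24, 12, by = -1.5))
#' @export
band_grid <- function(elevations, weights = NULL, band_width = NULL,
                      window = NULL) {
  elevations <- as.numeric(elevations)
  n <- length(elevations)
  if (n < 1L) stop("a band grid needs at least one band")
  if (anyNA(elevations)) stop("band elevations must not contain NA")
  if (anyDuplicated(elevations)) stop("duplicate band elevations")
  if (is.unsorted(elevations, strictly = TRUE))
    stop("band elevations must be strictly increasing")
  if (n >= 2L) {
    gaps <- diff(elevations)
    if (max(gaps) - min(gaps) > 1e-8 * max(gaps))
      stop("band elevations must be evenly spaced")
    inferred <- gaps[1L]
    if (is.null(band_width)) band_width <- inferred
    else if (abs(band_width - inferred) > 1e-8)
      stop("band_width does not match elevation spacing")
  } else if (is.null(band_width)) {
    band_width <- 200
  }
  if (is.null(weights)) weights <- rep(1, n)
  weights <- as.numeric(weights)
  if (length(weights) != n)
    stop("weights must have one value per band")
  if (anyNA(weights) || any(weights < 0))
    stop("weights must be non-negative and non-missing")
  if (is.null(window)) window <- c(1L, n)
  window <- as.integer(window)
  if (length(window) != 2L || window[1L] > window[2L] ||
      window[1L] < 1L || window[2L] > n)
    stop("window must be a contiguous, non-empty sub-range of bands")
  structure(
    list(elevations = elevations, band_width = band_width,
         weights = weights, window = window),
    class = "band_grid"
  )
}

#' @export
print.band_grid <- function(x, ...) {
  n <- n_bands(x)
  cat(sprintf("Elevation band grid: %d band%s of %g m, %g-%g m (edges)\n",
              n, if (n == 1L) "" else "s", x$band_width,
              min(x$elevations), max(x$elevations) + x$band_width))
  cat(sprintf("Sampled window: bands %d-%d (%g-%g m)\n",
              x$window[1L], x$window[2L],
              x$elevations[x$window[1L]],
              x$elevations[x$window[2L]] + x$band_width))
  w <- x$weights
  cat(sprintf("Weights: %s\n",
              paste(format(w, digits = 3, trim = TRUE), collapse = " ")))
  invisible(x)
}

#' Number of bands in a grid
#' @param grid A [band_grid()].
#' @return Integer band count.
#' @export
n_bands <- function(grid) length(grid$elevations)

#' Indices of the sampled window
#' @param grid A [band_grid()].
#' @return Integer vector of band indices inside the sampled window.
#' @export
window_bands <- function(grid) seq.int(grid$window[1L], grid$window[2L])

# map elevations (metres, band labels) to band indices; NA when unmatched
band_index <- function(grid, elevation_m, tol = 1e-6) {
  vapply(elevation_m, function(e) {
    hit <- which(abs(grid$elevations - e) <= tol)
    if (length(hit) == 1L) hit else NA_integer_
  }, integer(1L))
}

#' Read a band table CSV
#'
#' Expects one row per band with columns `band_elevation_m` and `mat_c`
#' (mean annual temperature, degrees Celsius, used as the environmental
#' weight). Rows may appear in any order; extra columns are ignored.
#'
#' @param path Path to a CSV file.
#' @return A [band_grid()] whose sampled window covers every band in the file.
#' @export
read_band_table <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  need <- c("band_elevation_m", "mat_c")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("band table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$band_elevation_m))
    stop("duplicate band labels in band table")
  ord <- order(tab$band_elevation_m)
  band_grid(tab$band_elevation_m[ord], weights = tab$mat_c[ord])
}

#' Write a band table CSV
#'
#' @param grid A [band_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_band_table <- function(grid, path) {
  utils::write.csv(
    data.frame(band_elevation_m = grid$elevations, mat_c = grid$weights),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Extend a grid to a wider model domain
#'
#' Null models may place ranges on a domain wider than the surveyed gradient
#' (e.g. 200-2800 m around a 600-2400 m survey). New bands are appended at
#' the same width; their weights are linearly extrapolated from the trend of
#' the supplied bands (ordinary least squares of weight on elevation) unless
#' given explicitly. The sampled window of the returned grid marks the bands
#' of the original grid.
#'
#' @param grid A [band_grid()] describing the surveyed bands.
#' @param domain_low_m,domain_high_m Domain edges in metres. The domain is
#'   the bands whose lower edges run from `domain_low_m` to
#'   `domain_high_m - band_width`. Both must align with the band lattice and
#'   cover the original grid.
#' @param weights Optional full weight vector for the extended grid,
#'   overriding extrapolation.
#' @return A [band_grid()] for the model domain.
#' @export
extend_grid <- function(grid, domain_low_m, domain_high_m, weights = NULL) {
  bw <- grid$band_width
  lo <- grid$elevations[1L]
  hi <- grid$elevations[n_bands(grid)] + bw
  if (domain_low_m > lo || domain_high_m < hi)
    stop("domain must cover the sampled grid")
  for (edge in c(domain_low_m, domain_high_m)) {
    if (abs((edge - lo) / bw - round((edge - lo) / bw)) > 1e-8)
      stop("domain edges must align with the band lattice")
  }
  elev <- seq(domain_low_m, domain_high_m - bw, by = bw)
  if (is.null(weights)) {
    if (n_bands(grid) >= 2L) {
      fit <- stats::lm(w ~ e,
                       data = data.frame(w = grid$weights,
                                         e = grid$elevations))
      weights <- stats::predict(fit, newdata = data.frame(e = elev))
    } else {
      weights <- rep(grid$weights, length(elev))
    }
    keep <- band_index(band_grid(elev), grid$elevations)
    weights[keep] <- grid$weights
    if (any(weights < 0))
      stop("extrapolated weights are negative; supply weights explicitly")
  }
  win <- range(band_index(band_grid(elev), grid$elevations))
  band_grid(elev, weights = weights, window = win)
}
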