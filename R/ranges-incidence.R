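#' Species elevational ranges
#'
#' Builds the canonical range table: one row per species with the extreme
#' occupied band indices, the interpolated band count and the range midpoint
#' in metres. Ranges are assumed interpolated (contiguous between the
#' extremes) unless a separate raw occupied-band count is supplied.
#'
#' @param species Character vector of species identifiers.
#' @param min_band,max_band Integer band indices of the lowest and highest
#'   occupied bands on `grid`.
#' @param grid The [band_grid()] the indices refer to.
#' @param raw_num_bands Optional integer vector of raw occupied-band counts
#'   (before interpolation); defaults to the interpolated count.
#'
#' @return A `species_ranges` data frame with columns `species`, `min_band`,
#'   `max_band`, `size` (interpolated band count), `raw_size`, `mid_m`.
#' @export
species_ranges <- function(species, min_band, max_band, grid,
                           raw_num_bands = NULL) {
  species <- as.character(species)
  min_band <- as.integer(min_band)
  max_band <- as.integer(max_band)
  n <- length(species)
  if (length(min_band) != n || length(max_band) != n)
    stop("species, min_band and max_band must have equal length")
  if (anyDuplicated(species)) stop("duplicate species identifiers")
  if (any(min_band > max_band)) {
    bad <- species[min_band > max_band]
    stop("min band above max band for: ", paste(bad, collapse = ", "))
  }
  if (any(min_band < 1L) || any(max_band > n_bands(grid)))
    stop("band indices outside the grid")
  size <- max_band - min_band + 1L
  if (is.null(raw_num_bands)) raw_num_bands <- size
  raw_num_bands <- as.integer(raw_num_bands)
  if (any(raw_num_bands < 1L) || any(raw_num_bands > size))
    stop("raw band counts must lie in [1, interpolated size]")
  mid_m <- (grid$elevations[min_band] + grid$elevations[max_band]) / 2
  out <- data.frame(
    species = species, min_band = min_band, max_band = max_band,
    size = size, raw_size = raw_num_bands, mid_m = mid_m,
    stringsAsFactors = FALSE
  )
  class(out) <- c("species_ranges", "data.frame")
  attr(out, "grid") <- grid
  out
}

#' Read a species-range table CSV
#'
#' The expected dialect has columns `species`, `min`, `max`, `range`, `mid`
#' and `num_bands`, with `min`/`max`/`mid` in metres (band labels) and
#' `num_bands` the interpolated occupied-band count. `range`, `mid` and
#' `num_bands` are recomputed from `min`/`max` and checked against the file.
#'
#' @param path Path to a CSV file.
#' @param grid The [band_grid()] the elevations must map onto.
#' @return A [species_ranges()] table.
#' @export
read_ranges <- function(path, grid) {
  tab <- utils::read.csv(path, check.names = FALSE)
  need <- c("species", "min", "max", "num_bands")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("range table is missing column(s): ", paste(miss, collapse = ", "))
  if (any(tab$min > tab$max)) {
    bad <- tab$species[tab$min > tab$max]
    stop("min elevation above max for: ", paste(bad, collapse = ", "))
  }
  lo <- band_index(grid, tab$min)
  hi <- band_index(grid, tab$max)
  unmapped <- is.na(lo) | is.na(hi)
  if (any(unmapped))
    stop("elevations not matching any band for: ",
         paste(tab$species[unmapped], collapse = ", "))
  rng <- species_ranges(tab$species, lo, hi, grid)
  if (any(rng$size != tab$num_bands)) {
    bad <- tab$species[rng$size != tab$num_bands]
    warning("num_bands in file disagrees with min/max for: ",
            paste(bad, collapse = ", "), "; recomputed values kept")
  }
  rng
}

#' Write a species-range table CSV
#'
#' Emits the `species, min, max, range, mid, num_bands` dialect, elevations
#' as band labels in metres.
#'
#' @param ranges A [species_ranges()] table.
#' @param path Output path.
#' @param grid Grid to resolve band labels; defaults to the table's own.
#' @return `path`, invisibly.
#' @export
write_ranges <- function(ranges, path, grid = attr(ranges, "grid")) {
  min_m <- grid$elevations[ranges$min_band]
  max_m <- grid$elevations[ranges$max_band]
  utils::write.csv(
    data.frame(species = ranges$species, min = min_m, max = max_m,
               range = max_m - min_m, mid = (min_m + max_m) / 2,
               num_bands = ranges$size),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Range-size frequency summary
#'
#' Tabulates interpolated range sizes and reports the share of the pool at or
#' below a size threshold (small-ranged species, by default up to three
#' bands, the group a weighting-by-small-ranges shortcut would rely on).
#'
#' @param ranges A [species_ranges()] table.
#' @param small_max Band-count threshold defining "small" ranges.
#' @return A list with `counts` (named table of sizes) and `small_share`.
#' @export
range_size_summary <- function(ranges, small_max = 3L) {
  counts <- table(factor(ranges$size, levels = seq_len(max(ranges$size))))
  list(counts = counts,
       small_share = mean(ranges$size <= small_max))
}

#' Band-by-species incidence matrix
#'
#' @param cells Integer 0/1 matrix, bands in rows, species in columns.
#' @param grid The [band_grid()] for the rows.
#' @param species_ids Column identifiers; taken from `colnames(cells)` when
#'   absent.
#' @return An `incidence_matrix` object.
#' @export
incidence_matrix <- function(cells, grid, species_ids = colnames(cells)) {
  cells <- as.matrix(cells)
  if (nrow(cells) != n_bands(grid))
    stop("incidence matrix must have one row per band")
  if (!all(cells %in% c(0L, 1L)))
    stop("incidence cells must be 0/1")
  if (is.null(species_ids))
    species_ids <- paste0("sp", seq_len(ncol(cells)))
  if (any(colSums(cells) < 1L)) {
    bad <- species_ids[colSums(cells) < 1L]
    stop("all-zero species column(s): ", paste(bad, collapse = ", "))
  }
  storage.mode(cells) <- "integer"
  dimnames(cells) <- list(format(grid$elevations, trim = TRUE), species_ids)
  structure(list(grid = grid, species_ids = species_ids, cells = cells),
            class = "incidence_matrix")
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat(sprintf("Incidence matrix: %d bands x %d species, fill %d\n",
              nrow(x$cells), ncol(x$cells), matrix_fill(x)))
  invisible(x)
}

#' Matrix fill (count of occupied cells)
#' @param x An [incidence_matrix()].
#' @return Integer number of 1-cells.
#' @export
matrix_fill <- function(x) sum(x$cells)

#' Interpolate ranges into an incidence matrix
#'
#' Each species occupies exactly the contiguous block of bands between its
#' recorded extremes.
#'
#' @param ranges A [species_ranges()] table.
#' @param grid The [band_grid()] to realise the matrix on.
#' @return An [incidence_matrix()] with fill equal to the sum of range sizes.
#' @export
ranges_to_incidence <- function(ranges, grid = attr(ranges, "grid")) {
  if (nrow(ranges) == 0L) stop("empty range list")
  cells <- matrix(0L, n_bands(grid), nrow(ranges))
  for (j in seq_len(nrow(ranges)))
    cells[ranges$min_band[j]:ranges$max_band[j], j] <- 1L
  incidence_matrix(cells, grid, ranges$species)
}

#' Recover species ranges from an incidence matrix
#'
#' The inverse mapping for raw (possibly discontinuous) occupancy: per
#' species the extreme occupied bands, the raw occupied-band count and the
#' interpolated count.
#'
#' @param x An [incidence_matrix()].
#' @return A [species_ranges()] table (with `raw_size` preserved).
#' @export
incidence_to_ranges <- function(x) {
  if (ncol(x$cells) < 1L) stop("incidence matrix has no species")
  occ <- apply(x$cells, 2L, function(col) range(which(col == 1L)))
  species_ranges(x$species_ids, occ[1L, ], occ[2L, ], x$grid,
                 raw_num_bands = colSums(x$cells))
}

#' Per-band species richness
#'
#' @param x An [incidence_matrix()] or [species_ranges()] table (the latter
#'   is interpolated first).
#' @param grid Grid for a `species_ranges` input.
#' @param window_only If `TRUE`, restrict to the sampled window.
#' @return Named numeric vector of per-band richness.
#' @export
band_richness <- function(x, grid = NULL, window_only = FALSE) {
  if (inherits(x, "species_ranges")) {
    if (is.null(grid)) grid <- attr(x, "grid")
    x <- ranges_to_incidence(x, grid)
  }
  r <- rowSums(x$cells)
  names(r) <- format(x$grid$elevations, trim = TRUE)
  if (window_only) r <- r[window_bands(x$grid)]
  r
}

#' Read an incidence CSV
#'
#' First column is the band elevation label, remaining columns one species
#' each with 0/1 cells.
#'
#' @param path Path to a CSV file.
#' @param grid Optional [band_grid()]; rebuilt with uniform weights from the
#'   file's elevations when absent.
#' @return An [incidence_matrix()].
#' @export
read_incidence <- function(path, grid = NULL) {
  tab <- utils::read.csv(path, check.names = FALSE)
  elev <- tab[[1L]]
  ord <- order(elev)
  cells <- as.matrix(tab[ord, -1L, drop = FALSE])
  if (is.null(grid)) grid <- band_grid(elev[ord])
  else if (!isTRUE(all.equal(as.numeric(elev[ord]), grid$elevations)))
    stop("incidence bands do not match the band grid")
  incidence_matrix(cells, grid, colnames(cells))
}

#' Write an incidence CSV
#' @param x An [incidence_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_incidence <- function(x, path) {
  out <- data.frame(band_elevation_m = x$grid$elevations,
                    x$cells, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
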