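#' Spectra set: aligned spectra on a shared wavenumber grid
#'
#' The central container of the package: a samples-by-wavenumbers intensity
#' matrix on one shared, strictly ascending wavenumber grid (cm-1), together
#' with per-sample metadata and a `kind` tag recording where the set stands in
#' the preprocessing chain (`reflectance` -> `absorbance` ->
#' `second_derivative`).
#'
#' Sample metadata is a data frame with columns `sample_id`, `level_id`
#' (concentration-level index), `replicate_id`, `state` (`wet`, `dry` or
#' `solution`), `casein_conc` and `nitrate_conc` (percent nitrogen w/w in the
#' impregnation solution) and `water_content` (mass fraction; `NA` unless
#' wet). Rows are kept in canonical `(level_id, replicate_id)` order; the
#' `(level_id, replicate_id)` pair must be unique.
#'
#' @param grid numeric vector of wavenumbers in cm-1. May be supplied
#'   descending (instrument order); it is stored ascending and the original
#'   direction recorded in the `"descending_input"` attribute.
#' @param intensities numeric matrix, one row per sample, `length(grid)`
#'   columns.
#' @param samples data frame of sample metadata (see Details).
#' @param kind one of `"reflectance"`, `"absorbance"`, `"second_derivative"`.
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(grid, intensities, samples, kind) {
  kind <- match.arg(kind, .kinds)
  grid <- as.numeric(grid)
  if (is.null(dim(intensities))) intensities <- matrix(intensities, nrow = 1)
  intensities <- as.matrix(intensities)
  if (length(grid) < 2L) stop("grid must have at least 2 points")
  d <- diff(grid)
  descending <- FALSE
  if (all(d < 0)) {
    grid <- rev(grid)
    intensities <- intensities[, rev(seq_along(grid)), drop = FALSE]
    descending <- TRUE
  } else if (!all(d > 0)) {
    stop("wavenumber grid is not strictly monotonic")
  }
  if (ncol(intensities) != length(grid))
    stop("intensity matrix has ", ncol(intensities),
         " columns but grid has ", length(grid), " points")
  samples <- .validate_samples(samples, nrow(intensities))
  if (kind == "reflectance" && any(intensities <= 0)) {
    bad <- which(intensities <= 0, arr.ind = TRUE)[1, ]
    stop("reflectance must be positive; sample '",
         samples$sample_id[bad[1]], "' at ", grid[bad[2]], " cm-1 is not")
  }
  ord <- order(samples$level_id, samples$replicate_id)
  samples <- samples[ord, , drop = FALSE]
  rownames(samples) <- NULL
  intensities <- intensities[ord, , drop = FALSE]
  rownames(intensities) <- samples$sample_id
  structure(
    list(grid = grid, intensities = intensities, samples = samples,
         kind = kind),
    descending_input = descending,
    class = "spectra_set")
}

.validate_samples <- function(samples, n) {
  samples <- as.data.frame(samples)
  need <- c("sample_id", "level_id", "replicate_id", "state",
            "casein_conc", "nitrate_conc")
  if (!"water_content" %in% names(samples)) samples$water_content <- NA_real_
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("sample metadata lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(samples) != n)
    stop("metadata has ", nrow(samples), " rows for ", n, " spectra")
  if (anyDuplicated(samples[c("level_id", "replicate_id")]))
    stop("(level_id, replicate_id) pairs must be unique within a set")
  if (any(samples$casein_conc < 0) || any(samples$nitrate_conc < 0))
    stop("concentrations must be non-negative")
  wc <- samples$water_content
  if (any(!is.na(wc) & (wc < 0 | wc > 1)))
    stop("water_content must lie in [0, 1]")
  if (!all(samples$state %in% .states))
    stop("state must be one of: ", paste(.states, collapse = ", "))
  samples$sample_id <- as.character(samples$sample_id)
  samples
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("<spectra_set> ", nrow(x$intensities), " spectra x ",
      length(x$grid), " points (", x$kind, ")\n", sep = "")
  cat("  grid: ", min(x$grid), "-", max(x$grid), " cm-1, median step ",
      stats::median(diff(x$grid)), " cm-1\n", sep = "")
  cat("  levels: ", length(unique(x$samples$level_id)),
      ", states: ", paste(unique(x$samples$state), collapse = "/"),
      "\n", sep = "")
  invisible(x)
}

#' Number of spectra in a set
#' @param set a [spectra_set()].
#' @return integer count of spectra (rows).
#' @export
n_spectra <- function(set) nrow(set$intensities)

#' Subset a spectra set by sample rows
#' @param set a [spectra_set()].
#' @param rows integer or logical row index.
#' @return a [spectra_set()] with the selected samples.
#' @export
subset_samples <- function(set, rows) {
  spectra_set(set$grid, set$intensities[rows, , drop = FALSE],
              set$samples[rows, , drop = FALSE], set$kind)
}

#' Linearly resample a spectra set onto a new grid
#'
#' Guarded fallback used when two sets that should share a grid (same
#' instrument, same settings) do not match exactly; interpolation is linear
#' and restricted to the overlap of the two grids.
#'
#' @param set a [spectra_set()].
#' @param new_grid ascending numeric wavenumber grid within the range of
#'   `set$grid`.
#' @return a [spectra_set()] on `new_grid`.
#' @export
resample_spectra <- function(set, new_grid) {
  new_grid <- as.numeric(new_grid)
  if (min(new_grid) < min(set$grid) || max(new_grid) > max(set$grid))
    stop("new grid extends beyond the measured range; refusing to extrapolate")
  m <- t(apply(set$intensities, 1,
               function(y) approx(set$grid, y, xout = new_grid)$y))
  spectra_set(new_grid, m, set$samples, set$kind)
}

.check_grid_match <- function(a, b, what = "sets") {
  if (length(a) != length(b) || max(abs(a - b)) > 1e-9)
    stop("wavenumber grids of the two ", what, " do not match")
  invisible(TRUE)
}
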