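#' Convert ratioed reflectance to apparent absorbance
#'
#' Applies `A = log10(1/R)` elementwise to a reflectance set already ratioed
#' against the white-reference measurement. The second-derivative and
#' correlation stages also run directly on reflectance if preferred
#' (`use_absorbance = FALSE` in [pipeline_config()]).
#'
#' @param set a reflectance [spectra_set()].
#' @return an absorbance [spectra_set()].
#' @export
to_absorbance <- function(set) {
  if (set$kind != "reflectance")
    stop("to_absorbance expects a reflectance set, got ", set$kind)
  if (any(set$intensities <= 0)) {
    bad <- which(set$intensities <= 0, arr.ind = TRUE)[1, ]
    stop("non-positive reflectance for sample '",
         set$samples$sample_id[bad[1]], "' at ", set$grid[bad[2]], " cm-1")
  }
  spectra_set(set$grid, log10(1 / set$intensities), set$samples, "absorbance")
}

#' Savitzky-Golay second derivative of a spectra set
#'
#' Local least-squares polynomial differentiation on a uniform grid: within
#' each window of `window` points a polynomial of order `polyorder` is fitted
#' and its second derivative read off at the window center. The filter
#' coefficients come from [signal::sgolay()]; the result is divided by the
#' squared grid step so intensities are in (input units)/(cm-1)^2 and
#' invariant to resampling density. The `(window-1)/2` edge points on each
#' side, where no centered window exists, are dropped rather than padded; the
#' trim count is recorded in the `"edge_trimmed"` attribute.
#'
#' @param set a reflectance or absorbance [spectra_set()].
#' @param window odd window length in points (11 for the NIR leaf-model
#'   settings, 17 for MIR solutions).
#' @param polyorder polynomial order, at least 2 and less than `window`.
#' @return a `second_derivative` [spectra_set()] on the trimmed grid.
#' @export
second_derivative <- function(set, window = 11L, polyorder = 2L) {
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L) stop("window must be odd, got ", window)
  if (polyorder < 2L) stop("polyorder must be >= 2 for a second derivative")
  if (window <= polyorder) stop("window must exceed polyorder")
  if (window > length(set$grid))
    stop("window (", window, ") exceeds grid length (", length(set$grid), ")")
  if (set$kind == "second_derivative")
    stop("set has already been differentiated")
  steps <- diff(set$grid)
  h <- stats::median(steps)
  if (max(abs(steps - h)) > 0.01 * h)
    stop("grid not uniform within 1% of the median step; resample first ",
         "(see resample_spectra)")
  half <- (window - 1L) %/% 2L
  co <- signal::sgolay(p = polyorder, n = window, m = 2)[half + 1L, ]
  keep <- (half + 1L):(length(set$grid) - half)
  d2 <- t(apply(set$intensities, 1, function(y) {
    as.numeric(stats::filter(y, co, sides = 2))[keep] / h^2
  }))
  out <- spectra_set(set$grid[keep], d2, set$samples, "second_derivative")
  attr(out, "edge_trimmed") <- half
  attr(out, "sg") <- list(window = window, polyorder = polyorder)
  out
}

#' Restrict a spectra set to a wavenumber interval
#'
#' Keeps the original grid points inside the closed interval `[lo, hi]`
#' (no resampling). The leaf-model analysis restricts NIR spectra to
#' 7500-4000 cm-1, where replicate variability of the second derivative is
#' low and the filter-paper and analyte combination/overtone bands sit.
#'
#' @param set a [spectra_set()].
#' @param lo,hi interval bounds in cm-1 (`lo < hi`).
#' @return a [spectra_set()] on the retained grid points.
#' @export
restrict_region <- function(set, lo, hi) {
  if (lo >= hi) stop("lo must be below hi")
  keep <- set$grid >= lo & set$grid <= hi
  if (!any(keep))
    stop("interval [", lo, ", ", hi, "] does not overlap the grid (",
         min(set$grid), "-", max(set$grid), " cm-1)")
  spectra_set(set$grid[keep], set$intensities[, keep, drop = FALSE],
              set$samples, set$kind)
}

#' Replicate variability spectrum (relative standard deviation)
#'
#' Per-wavenumber sample standard deviation divided by the mean across
#' repeated measurements of one physical sample. For second-derivative
#' spectra this is the diagnostic used to decide which spectral region is
#' stable enough to carry the calibration. Wavenumbers where the mean is
#' numerically zero are flagged undefined (`NA`).
#'
#' @param set a [spectra_set()] whose rows are repeated measurements.
#' @param floor relative numeric floor on `|mean|` (times the largest
#'   `|mean|` on the grid) below which the ratio is undefined.
#' @return object of class `variability_spectrum`: list with `grid`, `cv`
#'   and `n` (number of replicates).
#' @export
replicate_variability <- function(set, floor = 1e-12) {
  n <- n_spectra(set)
  if (n < 2L) stop("need at least 2 replicate spectra, got ", n)
  mu <- colMeans(set$intensities)
  s <- apply(set$intensities, 2, sd)
  cv <- s / mu
  cv[abs(mu) <= floor * max(abs(mu))] <- NA_real_
  structure(list(grid = set$grid, cv = cv, n = n),
            class = "variability_spectrum")
}

#' Average replicate spectra within each concentration level
#'
#' Collapses a set to one mean spectrum per `level_id` (used upstream of the
#' two-dimensional correlation analysis, which takes one spectrum per
#' perturbation level). The metadata keeps the first replicate's sample
#' fields plus an `n_averaged` column.
#'
#' @param set a [spectra_set()].
#' @return a [spectra_set()] with one spectrum per level.
#' @export
average_replicates <- function(set) {
  if (n_spectra(set) == 0L) stop("empty spectra set")
  lv <- set$samples$level_id
  levels_u <- sort(unique(lv))
  m <- t(vapply(levels_u,
                function(l) colMeans(set$intensities[lv == l, , drop = FALSE]),
                numeric(length(set$grid))))
  samples <- set$samples[match(levels_u, lv), , drop = FALSE]
  samples$replicate_id <- 1L
  samples$n_averaged <- as.integer(table(factor(lv, levels = levels_u)))
  samples$sample_id <- paste0("level", levels_u, "_mean")
  out <- spectra_set(set$grid, m, samples, set$kind)
  attr(out, "edge_trimmed") <- attr(set, "edge_trimmed")
  out
}
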