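#' Per-wavenumber correlation spectrum against analyte concentration
#'
#' Pearson correlation, at each wavenumber, between the second-derivative
#' intensity and the analyte concentration across samples (replicates enter
#' individually unless the set was averaged upstream). Wavenumbers with zero
#' intensity variance are flagged undefined (`NA`) and are never selected.
#'
#' @param set a `second_derivative` [spectra_set()].
#' @param analyte `"casein"` or `"nitrate"`.
#' @return object of class `correlation_spectrum`: list with `grid`, `r`,
#'   `n` and `analyte`.
#' @export
correlation_spectrum <- function(set, analyte = c("casein", "nitrate")) {
  analyte <- match.arg(analyte)
  n <- n_spectra(set)
  if (n < 3L) stop("need at least 3 samples, got ", n)
  y <- set$samples[[paste0(analyte, "_conc")]]
  if (sd(y) == 0) stop("analyte concentrations are constant; ",
                       "no correlation is defined")
  r <- suppressWarnings(as.numeric(cor(set$intensities, y)))
  r[apply(set$intensities, 2, sd) == 0] <- NA_real_
  structure(list(grid = set$grid, r = r, n = n, analyte = analyte),
            class = "correlation_spectrum")
}

.band_flags <- c("from_threshold", "from_2d", "common_wet_dry", "extended")

#' Construct a band set
#'
#' A band set is an ordered list of disjoint inclusive index intervals
#' `[start, end]` on a stated wavenumber grid, with per-band provenance
#' flags recording which selection steps produced it. A single isolated
#' point is a legal one-point band.
#'
#' @param bands data frame with integer columns `start`, `end` (1-based,
#'   inclusive, `start <= end`) and optionally logical provenance columns
#'   `from_threshold`, `from_2d`, `common_wet_dry`, `extended`.
#' @param grid the wavenumber grid the indices refer to.
#' @param analyte `"casein"` or `"nitrate"`.
#' @return object of class `band_set`.
#' @export
band_set <- function(bands, grid, analyte = c("casein", "nitrate")) {
  analyte <- match.arg(analyte)
  bands <- as.data.frame(bands)
  if (nrow(bands)) {
    bands$start <- as.integer(bands$start)
    bands$end <- as.integer(bands$end)
    if (any(bands$start > bands$end)) stop("band start exceeds end")
    if (any(bands$start < 1L) || any(bands$end > length(grid)))
      stop("band indices outside grid bounds")
    bands <- bands[order(bands$start), , drop = FALSE]
    if (nrow(bands) > 1L && any(bands$start[-1] <= bands$end[-nrow(bands)]))
      stop("bands must be disjoint")
  } else {
    bands <- data.frame(start = integer(0), end = integer(0))
  }
  for (f in .band_flags)
    if (!f %in% names(bands)) bands[[f]] <- logical(nrow(bands))
  rownames(bands) <- NULL
  structure(list(bands = bands[c("start", "end", .band_flags)],
                 grid = grid, analyte = analyte),
            class = "band_set")
}

#' @export
print.band_set <- function(x, ...) {
  cat("<band_set> ", nrow(x$bands), " band(s), ", length(band_indices(x)),
      " grid points, analyte: ", x$analyte, "\n", sep = "")
  if (nrow(x$bands)) {
    rng <- sprintf("%g-%g cm-1 [%d,%d]", x$grid[x$bands$start],
                   x$grid[x$bands$end], x$bands$start, x$bands$end)
    cat(paste0("  ", rng, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Covered grid indices of a band set
#' @param bs a [band_set()].
#' @return sorted integer vector of all indices covered by the bands.
#' @export
band_indices <- function(bs) {
  if (!nrow(bs$bands)) return(integer(0))
  sort(unique(unlist(mapply(seq, bs$bands$start, bs$bands$end,
                            SIMPLIFY = FALSE))))
}

# maximal contiguous runs of TRUE -> data.frame(start, end)
.mask_runs <- function(mask) {
  mask[is.na(mask)] <- FALSE
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

# rebuild a band_set from an index mask, OR-ing provenance over sources
.bands_from_mask <- function(mask, grid, analyte, sources = list(),
                             set_flag = NULL) {
  runs <- .mask_runs(mask)
  for (f in .band_flags) runs[[f]] <- logical(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    idx <- runs$start[i]:runs$end[i]
    for (src in sources) {
      cov <- band_indices(src)
      for (f in .band_flags) {
        flagged <- unlist(mapply(seq, src$bands$start, src$bands$end,
                                 SIMPLIFY = FALSE)[src$bands[[f]]])
        if (length(intersect(idx, flagged))) runs[[f]][i] <- TRUE
      }
    }
  }
  if (!is.null(set_flag)) runs[[set_flag]] <- rep(TRUE, nrow(runs))
  band_set(runs, grid, analyte)
}

#' Threshold a correlation spectrum into bands
#'
#' Maximal contiguous runs of wavenumbers with `|r| >= tau` become bands
#' (undefined points break runs). The leaf-model analysis uses `tau = 0.8`.
#'
#' @param cs a [correlation_spectrum()].
#' @param tau absolute-correlation threshold in (0, 1].
#' @param analyte analyte tag for the result; defaults to the correlation
#'   spectrum's analyte.
#' @return a [band_set()] with `from_threshold` set.
#' @export
threshold_bands <- function(cs, tau = 0.8, analyte = cs$analyte) {
  if (tau <= 0 || tau > 1) stop("tau must be in (0, 1]")
  mask <- !is.na(cs$r) & abs(cs$r) >= tau
  .bands_from_mask(mask, cs$grid, analyte, set_flag = "from_threshold")
}

.covered_mask <- function(bs) {
  mask <- logical(length(bs$grid))
  mask[band_indices(bs)] <- TRUE
  mask
}

#' Intersect two band sets (wet/dry common bands)
#'
#' Pointwise intersection of the covered index sets, re-segmented into
#' maximal runs. Used to keep only bands common to the dry and wet leaf
#' models, i.e. robust to water content. If the grids differ (they should
#' not when both states were measured with the same settings), resample the
#' second set onto the first grid before calling.
#'
#' @param a,b [band_set()] objects on the same grid and analyte.
#' @return a [band_set()] with `common_wet_dry` set.
#' @export
intersect_bands <- function(a, b) {
  .check_grid_match(a$grid, b$grid, "band sets")
  if (a$analyte != b$analyte) stop("band sets target different analytes")
  .bands_from_mask(.covered_mask(a) & .covered_mask(b), a$grid, a$analyte,
                   sources = list(a, b), set_flag = "common_wet_dry")
}

#' Intersect a band set with two-dimensional hotspot indices
#'
#' Retains only the band points also present in the hotspot index set from
#' the hetero-spectral correlation map (see [twod_hotspots()]);
#' re-segments into maximal runs. Pointwise AND, so the order of the
#' threshold and 2D intersection steps does not matter.
#'
#' @param bs a [band_set()].
#' @param hotspots integer indices on the same grid.
#' @return a [band_set()] with `from_2d` set.
#' @export
intersect_with_2d <- function(bs, hotspots) {
  hotspots <- as.integer(hotspots)
  if (length(hotspots) &&
      (min(hotspots) < 1L || max(hotspots) > length(bs$grid)))
    stop("hotspot indices outside the band set's grid")
  hmask <- logical(length(bs$grid))
  hmask[hotspots] <- TRUE
  .bands_from_mask(.covered_mask(bs) & hmask, bs$grid, bs$analyte,
                   sources = list(bs), set_flag = "from_2d")
}

#' Extend every band by k points on each side
#'
#' Each interval `[s, e]` becomes `[s - k, e + k]`, clipped to the grid;
#' overlapping results are merged. The leaf-model nitrate bands are very
#' narrow and were extended by one point before regression.
#'
#' @param bs a [band_set()].
#' @param k non-negative number of points to add on each side.
#' @return a [band_set()] with `extended` set (when `k > 0`).
#' @export
extend_bands <- function(bs, k = 1L) {
  k <- as.integer(k)
  if (k < 0L) stop("k must be non-negative")
  if (k == 0L || !nrow(bs$bands)) return(bs)
  mask <- logical(length(bs$grid))
  for (i in seq_len(nrow(bs$bands))) {
    s <- max(1L, bs$bands$start[i] - k)
    e <- min(length(bs$grid), bs$bands$end[i] + k)
    mask[s:e] <- TRUE
  }
  .bands_from_mask(mask, bs$grid, bs$analyte, sources = list(bs),
                   set_flag = "extended")
}

#' Extract the regression matrix for a band set
#'
#' Concatenates the intensities at all covered indices, ascending in
#' wavenumber; column names carry the wavenumbers for traceability.
#'
#' @param set a [spectra_set()] on the band set's grid.
#' @param bs a non-empty [band_set()].
#' @return numeric matrix, samples x selected points.
#' @export
extract_band_matrix <- function(set, bs) {
  .check_grid_match(set$grid, bs$grid, "set and band set")
  idx <- band_indices(bs)
  if (!length(idx))
    stop("empty band set: too few data points for a PLSR calibration")
  m <- set$intensities[, idx, drop = FALSE]
  colnames(m) <- sprintf("%g", set$grid[idx])
  m
}

#' Write a band set as CSV
#' @param bs a [band_set()].
#' @param path output CSV (columns `analyte, start_cm-1, end_cm-1,
#'   start_idx, end_idx` plus flags).
#' @return invisibly, `path`.
#' @export
write_band_set <- function(bs, path) {
  b <- bs$bands
  out <- data.frame(analyte = rep(bs$analyte, nrow(b)),
                    `start_cm-1` = bs$grid[b$start],
                    `end_cm-1` = bs$grid[b$end],
                    start_idx = b$start, end_idx = b$end,
                    check.names = FALSE)
  out <- cbind(out, b[.band_flags])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
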