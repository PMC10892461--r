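#' Build a perturbation series for two-dimensional correlation analysis
#'
#' Orders one spectrum per concentration level by ascending concentration of
#' the chosen analyte and subtracts the per-wavenumber mean across levels,
#' yielding the dynamic spectra of generalized two-dimensional correlation
#' spectroscopy. Feed per-level means (see [average_replicates()]) rather
#' than raw replicates.
#'
#' @param set a [spectra_set()] with exactly one spectrum per level.
#' @param perturbation `"casein"` or `"nitrate"`: which analyte's
#'   concentration orders the series.
#' @return object of class `perturbation_series`: list with `grid`,
#'   `dynamic` (levels x wavenumbers, column means zero), `levels`
#'   (ascending concentrations), `reference` (subtracted mean spectrum) and
#'   `analyte`.
#' @export
make_series <- function(set, perturbation = c("casein", "nitrate")) {
  perturbation <- match.arg(perturbation)
  if (anyDuplicated(set$samples$level_id))
    stop("series requires one spectrum per level; average replicates first")
  m <- n_spectra(set)
  if (m < 2L) stop("need at least 2 perturbation levels, got ", m)
  conc <- set$samples[[paste0(perturbation, "_conc")]]
  ord <- order(conc, set$samples$level_id)
  x <- set$intensities[ord, , drop = FALSE]
  ref <- colMeans(x)
  structure(
    list(grid = set$grid, dynamic = sweep(x, 2, ref), levels = conc[ord],
         reference = ref, analyte = perturbation),
    class = "perturbation_series")
}

.check_series_pair <- function(a, b) {
  if (nrow(a$dynamic) != nrow(b$dynamic))
    stop("series have different level counts: ", nrow(a$dynamic), " vs ",
         nrow(b$dynamic))
  mism <- which(abs(a$levels - b$levels) >
                  1e-9 * pmax(abs(a$levels), abs(b$levels), 1e-300))
  if (length(mism))
    stop("perturbation values misaligned at level ", mism[1], ": ",
         a$levels[mism[1]], " vs ", b$levels[mism[1]])
  invisible(nrow(a$dynamic))
}

#' Synchronous two-dimensional correlation map
#'
#' The synchronous intensity is the covariance-style inner product of the two
#' dynamic traces over the perturbation levels,
#' `Phi(v1, v2) = sum_k a_k(v1) b_k(v2) / (m - 1)`. For the hetero-spectral
#' leaf-model analysis, series `a` is the NIR leaf-model series and `b` the
#' MIR solution series of the same analyte ladder; the concentration level is
#' the common perturbation axis.
#'
#' @param a,b [make_series()] objects with matching level designs.
#' @return numeric matrix `length(a$grid)` x `length(b$grid)`.
#' @export
synchronous <- function(a, b) {
  m <- .check_series_pair(a, b)
  crossprod(a$dynamic, b$dynamic) / (m - 1)
}

#' Asynchronous two-dimensional correlation map
#'
#' `Psi = A' N B / (m - 1)` with `N` the Hilbert-Noda matrix
#' (`N[j,k] = 0` if `j == k`, else `1 / (pi (k - j))`). Out-of-phase
#' intensity variation shows up here; fully in-phase series give a null map.
#'
#' @inheritParams synchronous
#' @return numeric matrix `length(a$grid)` x `length(b$grid)`.
#' @export
asynchronous <- function(a, b) {
  m <- .check_series_pair(a, b)
  if (m < 3L)
    warning("asynchronous map with m = ", m,
            " perturbation levels is not meaningful")
  crossprod(a$dynamic, hilbert_noda(m) %*% b$dynamic) / (m - 1)
}

#' Hilbert-Noda transformation matrix
#' @param m number of perturbation levels.
#' @return `m` x `m` matrix with `0` on the diagonal and `1/(pi*(k-j))` off
#'   it.
#' @export
hilbert_noda <- function(m) {
  jk <- outer(seq_len(m), seq_len(m), function(j, k) k - j)
  n <- 1 / (pi * jk)
  n[jk == 0L] <- 0
  n
}

#' Both two-dimensional correlation maps at once
#'
#' @inheritParams synchronous
#' @return object of class `twod_map`: list with `axis1`, `axis2`
#'   (wavenumber grids), `sync`, `async` and `m`.
#' @export
twod_map <- function(a, b) {
  structure(
    list(axis1 = a$grid, axis2 = b$grid, sync = synchronous(a, b),
         async = asynchronous(a, b), m = nrow(a$dynamic)),
    class = "twod_map")
}

#' @export
print.twod_map <- function(x, ...) {
  cat("<twod_map> ", length(x$axis1), " x ", length(x$axis2),
      " points, m = ", x$m, " levels\n", sep = "")
  cat("  |sync| max ", signif(max(abs(x$sync)), 4),
      ", |async| max ", signif(max(abs(x$async)), 4), "\n", sep = "")
  invisible(x)
}

#' Write a two-dimensional map as long-format CSV
#' @param map a [twod_map()].
#' @param path output CSV path (columns `nu1, nu2, sync, async`).
#' @return invisibly, `path`.
#' @export
write_twod_map <- function(map, path) {
  fmt <- function(x) sprintf("%.17g", x)
  out <- data.frame(
    nu1 = fmt(rep(map$axis1, times = length(map$axis2))),
    nu2 = fmt(rep(map$axis2, each = length(map$axis1))),
    sync = fmt(as.numeric(map$sync)),
    async = fmt(as.numeric(map$async)))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split the NIR working region into the five analysis regions
#'
#' The 7500-4000 cm-1 NIR region is analyzed in five sub-regions with
#' boundaries 7500, 6890, 5553, 5142, 4439 and 4000 cm-1. Each boundary is
#' snapped to the nearest grid point; a boundary point belongs to the
#' higher-wavenumber region (the lowest boundary closes the last region).
#' Because the Savitzky-Golay step trims grid edges, a boundary may sit
#' slightly outside the working grid; snapping within `snap_tol` covers that.
#'
#' @param grid ascending wavenumber grid.
#' @param boundaries descending boundary wavenumbers (cm-1).
#' @param snap_tol largest allowed distance (cm-1) between a boundary and
#'   its nearest grid point.
#' @return data frame with one row per region: `region`, `hi_cm`, `lo_cm`
#'   (snapped bounds) and `start`, `end` (ascending-grid index range,
#'   inclusive).
#' @export
split_nir_regions <- function(grid,
                              boundaries = c(7500, 6890, 5553, 5142, 4439,
                                             4000),
                              snap_tol = 50) {
  if (is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly ascending")
  boundaries <- sort(as.numeric(boundaries), decreasing = TRUE)
  idx <- vapply(boundaries, function(b) which.min(abs(grid - b)), 0L)
  off <- abs(grid[idx] - boundaries)
  if (any(off > snap_tol))
    stop("grid does not cover boundary ", boundaries[which.max(off)],
         " cm-1 within ", snap_tol, " cm-1")
  nreg <- length(boundaries) - 1L
  out <- data.frame(region = seq_len(nreg),
                    hi_cm = grid[idx][-length(idx)],
                    lo_cm = grid[idx][-1])
  # ascending grid: region r spans indices (idx[r+1], idx[r]]; the lowest
  # boundary has no region below it and closes the final region
  starts <- idx[-1] + 1L
  starts[nreg] <- idx[length(idx)]
  out$start <- starts
  out$end <- idx[-length(idx)]
  if (any(out$start > out$end))
    stop("degenerate region on this grid; boundaries too close together")
  out
}

#' NIR hotspot indices from a hetero-spectral synchronous map
#'
#' For each NIR wavenumber the statistic is the largest absolute synchronous
#' intensity against any MIR wavenumber inside the analyte's fundamental
#' bands; within each of the five NIR analysis regions, the indices in the
#' top `q` quantile of that statistic are returned. This makes the
#' qualitative reading of a hetero-spectral correlation map ("NIR bands
#' correlated with the analyte's stable MIR bands") an explicit, tunable
#' rule.
#'
#' @param map a [twod_map()] with NIR on axis 1 and MIR on axis 2.
#' @param mir_bands numeric vector `c(lo, hi)` or list of such intervals
#'   (cm-1) on the MIR axis covering the analyte's fundamentals.
#' @param q fraction of each region's indices to keep, in (0, 1].
#' @param regions optional region table from [split_nir_regions()]; computed
#'   from `map$axis1` when missing.
#' @return sorted integer indices into `map$axis1`.
#' @export
twod_hotspots <- function(map, mir_bands, q = 0.25, regions = NULL) {
  if (is.numeric(mir_bands)) mir_bands <- list(mir_bands)
  if (!length(mir_bands)) stop("mir_bands must contain at least one interval")
  if (q <= 0 || q > 1) stop("q must be in (0, 1]")
  cols <- sort(unique(unlist(lapply(mir_bands, function(b) {
    which(map$axis2 >= min(b) & map$axis2 <= max(b))
  }))))
  if (!length(cols)) stop("mir_bands do not overlap the MIR axis")
  stat <- apply(abs(map$sync[, cols, drop = FALSE]), 1, max)
  if (is.null(regions)) regions <- split_nir_regions(map$axis1)
  hits <- integer(0)
  for (r in seq_len(nrow(regions))) {
    rng <- regions$start[r]:regions$end[r]
    thr <- quantile(stat[rng], probs = 1 - q, names = FALSE)
    hits <- c(hits, rng[stat[rng] >= thr])
  }
  sort(unique(hits))
}
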