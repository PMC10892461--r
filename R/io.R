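#' Read spectra from CSV or JCAMP-DX
#'
#' The canonical CSV layout has a first column `wavenumber_cm-1` and one
#' column per sample; the header row carries sample ids which are matched
#' against a metadata sidecar CSV (columns `sample_id`, `level_id`,
#' `replicate_id`, `state`, `casein_conc`, `nitrate_conc`, `water_content`).
#' Descending instrument-order axes are normalized to ascending and the
#' original direction recorded.
#'
#' The JCAMP-DX reader handles single-spectrum files with fixed-form
#' `##XYDATA=(X++(Y..Y))` blocks (no SQZ/DIF compression); metadata for the
#' spectrum is looked up in the sidecar by the file's `##TITLE`.
#'
#' @param path path to the spectra file (CSV) or a vector of JCAMP-DX paths.
#' @param meta_path path to the metadata sidecar CSV.
#' @param format `"csv"` or `"jcamp"`.
#' @param kind spectral kind of the stored intensities.
#' @return a [spectra_set()].
#' @seealso [write_spectra()]
#' @export
read_spectra <- function(path, meta_path, format = c("csv", "jcamp"),
                         kind = "reflectance") {
  format <- match.arg(format)
  meta <- read.csv(meta_path, stringsAsFactors = FALSE)
  meta$sample_id <- as.character(meta$sample_id)
  if (format == "csv") {
    tab <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) stop("spectra CSV needs a wavenumber column plus ",
                             "at least one sample column")
    grid <- as.numeric(tab[[1]])
    ids <- colnames(tab)[-1]
    m <- t(as.matrix(tab[, -1, drop = FALSE]))
  } else {
    specs <- lapply(path, read_jcamp)
    grids <- lapply(specs, `[[`, "grid")
    for (g in grids[-1]) .check_grid_match(grids[[1]], g, "JCAMP files")
    grid <- grids[[1]]
    ids <- vapply(specs, `[[`, "", "title")
    m <- do.call(rbind, lapply(specs, `[[`, "intensities"))
  }
  missing_ids <- setdiff(ids, meta$sample_id)
  if (length(missing_ids))
    stop("no metadata for sample id(s): ", paste(missing_ids, collapse = ", "))
  samples <- meta[match(ids, meta$sample_id), , drop = FALSE]
  spectra_set(grid, m, samples, kind)
}

#' Write a spectra set to CSV (plus metadata sidecar)
#'
#' Intensities and grid are written with `%.17g` formatting so a
#' `write_spectra()` / [read_spectra()] round trip is lossless for doubles.
#'
#' @param set a [spectra_set()].
#' @param path output spectra CSV path.
#' @param meta_path output metadata sidecar CSV path.
#' @return invisibly, `path`.
#' @export
write_spectra <- function(set, path, meta_path) {
  fmt <- function(x) sprintf("%.17g", x)
  out <- data.frame(`wavenumber_cm-1` = fmt(set$grid), check.names = FALSE)
  for (i in seq_len(n_spectra(set)))
    out[[set$samples$sample_id[i]]] <- fmt(set$intensities[i, ])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  meta <- set$samples
  for (col in c("casein_conc", "nitrate_conc", "water_content"))
    meta[[col]] <- fmt(meta[[col]])
  write.csv(meta, meta_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a single-spectrum JCAMP-DX file
#'
#' Minimal reader for `##XYDATA=(X++(Y..Y))` blocks in fixed (AFFN) form:
#' each data line is an abscissa value followed by consecutive ordinates.
#' `##XFACTOR`/`##YFACTOR` are applied; the per-line abscissa is checked
#' against the `##FIRSTX`/`##LASTX`/`##NPOINTS` grid.
#'
#' @param path path to a JCAMP-DX file.
#' @return list with `grid`, `intensities` and `title`.
#' @export
read_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ldr <- function(name, default = NA) {
    hit <- grep(paste0("^##", name, "="), lines, value = TRUE)
    if (!length(hit)) return(default)
    sub(paste0("^##", name, "=\\s*"), "", hit[1])
  }
  title <- ldr("TITLE", "")
  xf <- as.numeric(ldr("XFACTOR", "1"))
  yf <- as.numeric(ldr("YFACTOR", "1"))
  firstx <- as.numeric(ldr("FIRSTX"))
  lastx <- as.numeric(ldr("LASTX"))
  np <- as.integer(ldr("NPOINTS"))
  start <- grep("^##XYDATA=\\(X\\+\\+\\(Y\\.\\.Y\\)\\)", lines)
  if (!length(start)) stop("no ##XYDATA=(X++(Y..Y)) block in ", path)
  end <- grep("^##END", lines)
  end <- min(end[end > start[1]])
  body <- lines[(start[1] + 1L):(end - 1L)]
  y <- numeric(0)
  for (ln in body) {
    vals <- as.numeric(strsplit(trimws(ln), "[\\s,]+", perl = TRUE)[[1]])
    if (anyNA(vals)) stop("non-numeric JCAMP data line (compressed forms ",
                          "are not supported): ", ln)
    xline <- vals[1] * xf
    expect_x <- firstx + (lastx - firstx) * length(y) / (np - 1L)
    if (abs(xline - expect_x) > abs(lastx - firstx) / (np - 1L))
      stop("JCAMP line abscissa ", xline, " inconsistent with header grid")
    y <- c(y, vals[-1] * yf)
  }
  if (!is.na(np) && length(y) != np)
    stop("JCAMP NPOINTS=", np, " but ", length(y), " ordinates read")
  grid <- seq(firstx, lastx, length.out = length(y))
  list(grid = grid, intensities = y, title = title)
}
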