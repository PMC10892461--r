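#' Pipeline configuration
#'
#' Aggregates every tunable of the end-to-end analysis. Defaults follow the
#' leaf-model study settings: Savitzky-Golay second derivative with a
#' second-order polynomial and an 11-point window for NIR (17 for MIR),
#' working region 7500-4000 cm-1, correlation threshold 0.8, one-point band
#' extension, leave-one-out cross-validation with minimum-MAE factor choice.
#'
#' @param design a [design_spec()] describing the synthetic experiment; its
#'   `state` field is overridden per pipeline state.
#' @param analytes analytes to calibrate, subset of `c("casein",
#'   "nitrate")`.
#' @param states leaf-model states to process, subset of `c("dry", "wet")`.
#' @param window_nir,window_mir,polyorder Savitzky-Golay settings.
#' @param region NIR working region `c(lo, hi)` in cm-1.
#' @param use_absorbance convert reflectance to `log10(1/R)` before
#'   differentiation (the pipeline also runs directly on ratioed
#'   reflectance when `FALSE`).
#' @param tau absolute-correlation band-selection threshold.
#' @param hotspot_q per-region quantile fraction kept by
#'   [twod_hotspots()].
#' @param mir_bands named list of MIR fundamental intervals (cm-1) per
#'   analyte used by the hetero-spectral hotspot rule.
#' @param extension points added on each side of every selected band.
#' @param common_wet_dry intersect dry and wet band sets when both states
#'   are run (falls back to the per-state set if the intersection is
#'   empty).
#' @param max_components,grouping,scale PLS1 cross-validation settings
#'   (see [loo_cv()]; `per_sample` keeps all replicate acquisitions of a
#'   level in one fold).
#' @param include_baseline also fit the full-spectrum (no band selection)
#'   control calibration.
#' @param write_maps export the (large) two-dimensional correlation maps as
#'   long CSV.
#' @param seed master integer seed for every stochastic stage.
#' @param verbose log per-stage progress via `message()`.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(design = design_spec(),
                            analytes = c("casein", "nitrate"),
                            states = c("dry", "wet"),
                            window_nir = 11L, window_mir = 17L,
                            polyorder = 2L,
                            region = c(4000, 7500),
                            use_absorbance = TRUE,
                            tau = 0.8, hotspot_q = 0.25,
                            mir_bands = list(casein = c(1500, 1700),
                                             nitrate = c(1300, 1450)),
                            extension = 1L,
                            common_wet_dry = TRUE,
                            max_components = 10L,
                            grouping = c("per_sample", "per_spectrum"),
                            scale = FALSE,
                            include_baseline = FALSE,
                            write_maps = FALSE,
                            seed = 1L,
                            verbose = FALSE) {
  grouping <- match.arg(grouping)
  if (!inherits(design, "design_spec")) stop("design must be a design_spec")
  if (!length(analytes)) stop("analytes must not be empty")
  if (!all(analytes %in% .analytes))
    stop("analytes must be among: ", paste(.analytes, collapse = ", "))
  if (!length(states) || !all(states %in% c("dry", "wet")))
    stop("states must be a non-empty subset of dry/wet")
  if (tau <= 0 || tau > 1) stop("tau must be in (0, 1]")
  if (hotspot_q <= 0 || hotspot_q > 1) stop("hotspot_q must be in (0, 1]")
  miss <- setdiff(analytes, names(mir_bands))
  if (length(miss)) stop("mir_bands missing for: ",
                         paste(miss, collapse = ", "))
  if (length(region) != 2L || region[1] >= region[2])
    stop("region must be c(lo, hi) with lo < hi")
  structure(
    list(design = design, analytes = analytes, states = states,
         window_nir = as.integer(window_nir),
         window_mir = as.integer(window_mir),
         polyorder = as.integer(polyorder), region = as.numeric(region),
         use_absorbance = isTRUE(use_absorbance), tau = tau,
         hotspot_q = hotspot_q, mir_bands = mir_bands,
         extension = as.integer(extension),
         common_wet_dry = isTRUE(common_wet_dry),
         max_components = as.integer(max_components), grouping = grouping,
         scale = isTRUE(scale), include_baseline = isTRUE(include_baseline),
         write_maps = isTRUE(write_maps), seed = as.integer(seed),
         verbose = isTRUE(verbose)),
    class = "pipeline_config")
}

.log <- function(config, ...) if (config$verbose) message(...)

# deterministic per-state seed offsets derived from the master seed
.state_seed <- function(seed, state) {
  seed + switch(state, dry = 0L, wet = 5003L, solution = 1000003L)
}

# generate and preprocess everything the selection/calibration stages need
.prepare_inputs <- function(config) {
  prep <- list(nir = list())
  for (st in config$states) {
    d <- config$design
    d$state <- st
    d$seed <- .state_seed(config$seed, st)
    gen <- generate_nir_set(d)
    raw <- gen$set
    work <- if (config$use_absorbance) to_absorbance(raw) else raw
    d2 <- restrict_region(
      second_derivative(work, config$window_nir, config$polyorder),
      config$region[1], config$region[2])
    .log(config, "prepared NIR ", st, ": ", n_spectra(d2), " spectra x ",
         length(d2$grid), " points")
    prep$nir[[st]] <- list(raw = raw, d2 = d2, truth = gen$truth)
  }
  dm <- config$design
  dm$state <- "solution"
  dm$seed <- .state_seed(config$seed, "solution")
  mir <- generate_mir_set(dm)
  mir_d2 <- second_derivative(mir$set, config$window_mir, config$polyorder)
  .log(config, "prepared MIR solutions: ", n_spectra(mir_d2),
       " spectra x ", length(mir_d2$grid), " points")
  prep$mir <- list(raw = mir$set, d2 = mir_d2, truth = mir$truth)
  prep
}

# one analyte+state: 2D map, hotspots, correlation spectrum, raw band set
.select_state_bands <- function(analyte, state, prep, config) {
  nir_series <- make_series(average_replicates(prep$nir[[state]]$d2),
                            analyte)
  mir_series <- make_series(average_replicates(prep$mir$d2), analyte)
  map <- twod_map(nir_series, mir_series)
  hotspots <- twod_hotspots(map, config$mir_bands[[analyte]],
                            q = config$hotspot_q)
  cs <- correlation_spectrum(prep$nir[[state]]$d2, analyte)
  bands <- intersect_with_2d(threshold_bands(cs, config$tau), hotspots)
  list(map = map, hotspots = hotspots, cs = cs, bands = bands)
}

# fraction of the generator's true analyte NIR band centers (inside the
# working grid) covered by a band set
.band_recovery <- function(bs, truth, analyte) {
  centers <- truth$band_centers[[analyte]]$center
  centers <- centers[centers >= min(bs$grid) & centers <= max(bs$grid)]
  if (!length(centers)) return(NA_real_)
  idx <- vapply(centers, function(ct) which.min(abs(bs$grid - ct)), 0L)
  mean(idx %in% band_indices(bs))
}

#' Run the end-to-end band-selection and calibration pipeline
#'
#' Generates the paired synthetic NIR leaf-model and MIR solution sets,
#' preprocesses them (absorbance, Savitzky-Golay second derivative, region
#' restriction), runs the hetero-spectral two-dimensional correlation
#' analysis and the correlation-threshold band selection (with optional
#' wet/dry common-band intersection and band extension), and fits one
#' leave-one-out PLS1 calibration per analyte and state. When `outdir` is
#' given, band sets, calibration exports, optional 2D maps and a JSON
#' manifest with file checksums are written there.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional output directory (created if needed).
#' @return object of class `pipeline_report`: list with `config`,
#'   `selections` (per analyte/state: map, hotspots, correlation spectrum,
#'   raw bands), `final_bands`, `calibrations`, `band_recovery`,
#'   `common_band_fallback`, optional `baselines`, and `files`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  prep <- .prepare_inputs(config)
  report <- list(config = config, selections = list(), final_bands = list(),
                 calibrations = list(), band_recovery = list(),
                 common_band_fallback = list(), baselines = list())
  for (analyte in config$analytes) {
    sel <- lapply(setNames(config$states, config$states),
                  function(st) .select_state_bands(analyte, st, prep,
                                                   config))
    report$selections[[analyte]] <- sel
    common <- NULL
    fallback <- FALSE
    if (config$common_wet_dry && length(config$states) == 2L) {
      common <- intersect_bands(sel[["dry"]]$bands, sel[["wet"]]$bands)
      if (!nrow(common$bands)) {
        fallback <- TRUE
        common <- NULL
        .log(config, analyte, ": empty wet/dry common set, ",
             "falling back to per-state bands")
      }
    }
    report$common_band_fallback[[analyte]] <- fallback
    for (st in config$states) {
      base_bands <- if (!is.null(common)) common else sel[[st]]$bands
      final <- extend_bands(base_bands, config$extension)
      d2 <- prep$nir[[st]]$d2
      y <- d2$samples[[paste0(analyte, "_conc")]]
      cal <- loo_cv(extract_band_matrix(d2, final), y,
                    max_components = config$max_components,
                    grouping = config$grouping,
                    sample_ids = d2$samples$level_id)
      key <- paste(analyte, st, sep = "_")
      report$final_bands[[key]] <- final
      report$calibrations[[key]] <- cal
      report$band_recovery[[key]] <-
        .band_recovery(final, prep$nir[[st]]$truth, analyte)
      .log(config, key, ": ", nrow(final$bands), " band(s), ",
           length(band_indices(final)), " points, LOO R2 = ",
           signif(cal$r2_validation, 3))
      if (config$include_baseline) {
        report$baselines[[key]] <-
          loo_cv(d2$intensities, y,
                 max_components = config$max_components,
                 grouping = config$grouping,
                 sample_ids = d2$samples$level_id)
      }
    }
  }
  report$prep <- prep
  class(report) <- "pipeline_report"
  if (!is.null(outdir)) report$files <- .write_report(report, outdir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> seed ", x$config$seed, "\n", sep = "")
  for (key in names(x$calibrations)) {
    cal <- x$calibrations[[key]]
    cat(sprintf(
      "  %-16s %2d band pts, %d factor(s), LOO R2 = %.3f, MAE = %.4g\n",
      key, length(band_indices(x$final_bands[[key]])),
      cal$n_factors_chosen, cal$r2_validation, cal$mae))
  }
  invisible(x)
}

.write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  config <- report$config
  files <- character(0)
  for (key in names(report$calibrations)) {
    bp <- file.path(outdir, paste0("bands_", key, ".csv"))
    write_band_set(report$final_bands[[key]], bp)
    cp <- file.path(outdir, paste0("calibration_", key, ".csv"))
    jp <- file.path(outdir, paste0("calibration_", key, ".json"))
    st <- sub(".*_", "", key)
    write_calibration(report$calibrations[[key]], cp, jp,
                      sample_ids = report$prep$nir[[st]]$d2$samples$sample_id)
    files <- c(files, bp, cp, jp)
  }
  if (config$write_maps) {
    for (analyte in config$analytes) for (st in config$states) {
      mp <- file.path(outdir, paste0("twod_map_", analyte, "_", st, ".csv"))
      write_twod_map(report$selections[[analyte]][[st]]$map, mp)
      files <- c(files, mp)
    }
  }
  manifest <- list(
    package = "nirleaf",
    version = as.character(utils::packageVersion("nirleaf")),
    seed = config$seed,
    settings = config[c("analytes", "states", "window_nir", "window_mir",
                        "polyorder", "region", "use_absorbance", "tau",
                        "hotspot_q", "extension", "common_wet_dry",
                        "max_components", "grouping")],
    checksums = as.list(tools::md5sum(files)))
  names(manifest$checksums) <- basename(files)
  mf <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  c(files, mf)
}

#' Full-spectrum control calibration (no band selection)
#'
#' Leave-one-out PLS1 on the entire restricted working region, the negative
#' control against which band-selected calibration is compared: under heavy
#' non-analyte interference the full-spectrum model degrades while the
#' band-selected model holds up.
#'
#' @param config a [pipeline_config()].
#' @param analyte analyte to calibrate.
#' @param state leaf-model state to use.
#' @return a [loo_cv()] `calibration_result`.
#' @export
baseline_fullspectrum_run <- function(config, analyte = "casein",
                                      state = config$states[1]) {
  stopifnot(inherits(config, "pipeline_config"))
  config$states <- state
  prep <- .prepare_inputs(config)
  d2 <- prep$nir[[state]]$d2
  loo_cv(d2$intensities, d2$samples[[paste0(analyte, "_conc")]],
         max_components = config$max_components,
         grouping = config$grouping, sample_ids = d2$samples$level_id)
}
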