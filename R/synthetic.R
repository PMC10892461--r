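# evaluate expr under a fixed RNG state, restoring the caller's stream
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  expr
}

#' Default NIR wavenumber grid (9000-4000 cm-1, ~6 cm-1 step)
#' @param step grid step in cm-1.
#' @return ascending numeric grid.
#' @export
nir_grid <- function(step = 6) seq(4000, 9000, by = step)

#' Default MIR wavenumber grid (4000-800 cm-1, 4 cm-1 step)
#' @param step grid step in cm-1.
#' @return ascending numeric grid.
#' @export
mir_grid <- function(step = 4) seq(800, 4000, by = step)

#' Spectral component models for the synthetic leaf-model generator
#'
#' Each component (casein, nitrate, water, cellulose) carries NIR and MIR
#' band lists `(center, width, intensity)`; every band is rendered as a
#' Gaussian in absorbance, scaled linearly by the component's amount
#' (Beer-Lambert mixing by construction). Cellulose centers follow the
#' filter-paper combination/overtone bands (around 6700, 5200, 4700, 4400
#' and 4200 cm-1); analyte and water placements are generator parameters
#' chosen to be spectroscopically plausible, not measured ground truth.
#'
#' @return named list of component models.
#' @export
component_models <- function() {
  band <- function(...) {
    b <- data.frame(...)
    names(b) <- c("center", "width", "intensity")
    b
  }
  list(
    casein = list(
      name = "casein",
      nir_bands = band(c(4600, 4865, 5755, 6520), c(35, 35, 45, 50),
                       c(0.10, 0.12, 0.08, 0.05)),
      mir_bands = band(c(1240, 1540, 1650, 2930), c(30, 25, 25, 40),
                       c(0.20, 0.40, 0.50, 0.15))),
    nitrate = list(
      name = "nitrate",
      nir_bands = band(c(4150, 4330, 6100), c(25, 25, 35),
                       c(0.08, 0.10, 0.05)),
      mir_bands = band(c(1049, 1385), c(15, 20), c(0.10, 0.60))),
    water = list(
      name = "water",
      nir_bands = band(c(5150, 6900, 8350), c(110, 130, 180),
                       c(0.90, 0.60, 0.25)),
      mir_bands = band(c(1640, 2120, 3350), c(40, 80, 150),
                       c(0.50, 0.08, 1.20))),
    cellulose = list(
      name = "cellulose",
      nir_bands = band(c(4200, 4400, 4700, 5200, 6700), c(30, 30, 40, 45, 60),
                       c(0.25, 0.28, 0.22, 0.30, 0.18)),
      mir_bands = band(numeric(0), numeric(0), numeric(0))))
}

# sum of Gaussian bands on a grid, unit amount; tails truncated at 6 sigma
# (amplitude ~1e-8 of the peak) so a component's support is compact and
# noise-free spectra are exactly constant where a component is absent
.render_bands <- function(grid, bands) {
  a <- numeric(length(grid))
  for (i in seq_len(nrow(bands))) {
    z <- (grid - bands$center[i]) / bands$width[i]
    g <- exp(-0.5 * z^2)
    g[abs(z) > 6] <- 0
    a <- a + bands$intensity[i] * g
  }
  a
}

#' Design of a synthetic leaf-model experiment
#'
#' Encodes the study conditions the generator emulates: nine concentration
#' levels, six replicate acquisitions per level, wet/dry/solution states.
#' The casein ladder ascends 0.2-1.0 %N; the nitrate ladder spans
#' 0.05-0.45 %N in a fixed decorrelating permutation (correlation 0.17 with
#' the casein ladder) so the two analytes remain separable — a jointly
#' monotone ladder would confound their correlation spectra. Noise scales
#' are in absorbance units.
#'
#' @param n_levels number of concentration levels.
#' @param casein_levels,nitrate_levels concentration ladders (%N w/w),
#'   length `n_levels`.
#' @param n_replicates replicate acquisitions per level.
#' @param state `"dry"`, `"wet"` or `"solution"`.
#' @param water_content nominal wet-model water mass fraction.
#' @param water_jitter_sd per-sample sd of the wet water content.
#' @param noise_sd additive absorbance noise sd per point.
#' @param scatter_sd sd of the per-acquisition multiplicative gain.
#' @param baseline_sd scale of the random quadratic baseline drift.
#' @param cellulose_sd per-acquisition relative variation of the
#'   filter-paper contribution.
#' @param seed integer RNG seed; identical seeds give identical sets.
#' @return object of class `design_spec` (a validated list).
#' @export
design_spec <- function(n_levels = 9L,
                        casein_levels = seq(0.2, 1.0,
                                            length.out = n_levels),
                        nitrate_levels = seq(0.05, 0.45,
                                             length.out = n_levels)[
                                               .nitrate_perm(n_levels)],
                        n_replicates = 6L,
                        state = c("dry", "wet", "solution"),
                        water_content = 0.85,
                        water_jitter_sd = 0.02,
                        noise_sd = 3e-4,
                        scatter_sd = 0.01,
                        baseline_sd = 5e-3,
                        cellulose_sd = 0.02,
                        seed = 1L) {
  state <- match.arg(state)
  n_levels <- as.integer(n_levels)
  if (length(casein_levels) != n_levels ||
      length(nitrate_levels) != n_levels)
    stop("concentration ladders must have length n_levels")
  scales <- c(water_jitter_sd, noise_sd, scatter_sd, baseline_sd,
              cellulose_sd)
  if (any(scales < 0)) stop("noise scales must be non-negative")
  if (water_content <= 0 || water_content >= 1)
    stop("water_content must be in (0, 1)")
  structure(
    list(n_levels = n_levels, casein_levels = casein_levels,
         nitrate_levels = nitrate_levels,
         n_replicates = as.integer(n_replicates), state = state,
         water_content = water_content, water_jitter_sd = water_jitter_sd,
         noise_sd = noise_sd, scatter_sd = scatter_sd,
         baseline_sd = baseline_sd, cellulose_sd = cellulose_sd,
         seed = as.integer(seed)),
    class = "design_spec")
}

# fixed decorrelating permutation for the nitrate ladder
.nitrate_perm <- function(n) {
  if (n == 9L) return(c(3L, 7L, 1L, 9L, 5L, 2L, 8L, 4L, 6L))
  # deterministic low-correlation interleave for other lengths
  order(c(seq(2L, n, by = 2L), seq(1L, n, by = 2L)))
}

#' High-interference wet design preset
#'
#' A wet-model condition with strong non-analyte variation (instrument
#' noise, multiplicative scatter, sample-to-sample water content and
#' filter-paper variability, baseline drift) used as the negative-control
#' setting in which full-spectrum regression degrades while band-selected
#' regression holds up.
#'
#' @param seed integer RNG seed.
#' @return a [design_spec()].
#' @export
high_interference_design <- function(seed = 1L) {
  design_spec(state = "wet", noise_sd = 5e-3, scatter_sd = 0.05,
              water_jitter_sd = 0.15, baseline_sd = 0.03,
              cellulose_sd = 0.08, seed = seed)
}

# shared spectral assembly for one sample; amounts is a named numeric
# vector of component amounts, bands_field "nir_bands" or "mir_bands"
.assemble_abs <- function(grid, components, amounts, bands_field,
                          gain, base_coeffs, noise) {
  a <- numeric(length(grid))
  for (nm in names(amounts)) {
    if (amounts[[nm]] == 0) next
    a <- a + amounts[[nm]] *
      .render_bands(grid, components[[nm]][[bands_field]])
  }
  u <- 2 * (grid - min(grid)) / (max(grid) - min(grid)) - 1
  baseline <- base_coeffs[1] + base_coeffs[2] * u + base_coeffs[3] * u^2
  gain * a + baseline + noise
}

.truth_record <- function(grid, components, samples, analyte_scale) {
  centers <- lapply(components, function(cm) {
    b <- cm$nir_bands
    if (!nrow(b)) return(data.frame(center = numeric(0), index = integer(0)))
    data.frame(center = b$center,
               index = vapply(b$center,
                              function(ct) which.min(abs(grid - ct)), 0L))
  })
  list(grid = grid, band_centers = centers, samples = samples,
       analyte_scale = analyte_scale)
}

#' Generate a synthetic NIR leaf-model reflectance set
#'
#' Renders absorbance as a Beer-Lambert sum of Gaussian component bands
#' (casein, nitrate, water, cellulose) plus a seeded quadratic baseline,
#' per-acquisition multiplicative gain `1 + N(0, scatter_sd)` and additive
#' `N(0, noise_sd)` noise, then converts to reflectance `R = 10^(-A)`.
#' Drying removes water (small residual amplitude) and concentrates the
#' analytes in the paper matrix: their absorbance contribution is enriched
#' by `1 / (1 - water_content)` while the metadata keeps solution-%N
#' concentrations, so wet and dry calibrations share a reference scale.
#'
#' @param design a [design_spec()].
#' @param components a [component_models()] list.
#' @param grid NIR wavenumber grid.
#' @return list with `set` (a reflectance [spectra_set()]) and `truth`
#'   (grid, per-component NIR band-center indices, per-sample amounts,
#'   analyte enrichment scale).
#' @export
generate_nir_set <- function(design, components = component_models(),
                             grid = nir_grid()) {
  .with_seed(design$seed, {
    dry <- design$state == "dry"
    analyte_scale <- if (dry) 1 / (1 - design$water_content) else 1
    rows <- list(); meta <- list(); k <- 0L
    for (l in seq_len(design$n_levels)) {
      for (r in seq_len(design$n_replicates)) {
        k <- k + 1L
        wc <- if (design$state == "wet") {
          min(0.99, max(0.01, design$water_content +
                          rnorm(1, 0, design$water_jitter_sd)))
        } else NA_real_
        water_amp <- switch(design$state,
                            wet = wc, dry = 0.03, solution = 1.0)
        cell_amp <- if (design$state == "solution") 0 else
          1 + rnorm(1, 0, design$cellulose_sd)
        amounts <- c(
          casein = analyte_scale * design$casein_levels[l],
          nitrate = analyte_scale * design$nitrate_levels[l],
          water = water_amp, cellulose = cell_amp)
        gain <- 1 + rnorm(1, 0, design$scatter_sd)
        base_coeffs <- rnorm(3, 0, design$baseline_sd)
        noise <- rnorm(length(grid), 0, design$noise_sd)
        a <- .assemble_abs(grid, components, amounts, "nir_bands",
                           gain, base_coeffs, noise)
        refl <- 10^(-a)
        if (any(refl <= 0))
          stop("generator parameters give non-positive reflectance")
        rows[[k]] <- refl
        meta[[k]] <- data.frame(
          sample_id = sprintf("%s_L%d_R%d", design$state, l, r),
          level_id = l, replicate_id = r, state = design$state,
          casein_conc = design$casein_levels[l],
          nitrate_conc = design$nitrate_levels[l],
          water_content = wc)
      }
    }
    samples <- do.call(rbind, meta)
    set <- spectra_set(grid, do.call(rbind, rows), samples, "reflectance")
    list(set = set,
         truth = .truth_record(grid, components, samples, analyte_scale))
  })
}

#' Generate a synthetic MIR solution absorbance set
#'
#' ATR-style absorbance spectra of the impregnation solutions: analyte and
#' water bands only (no filter paper), water amplitude fixed across levels
#' (constant solvent), same noise model as [generate_nir_set()].
#'
#' @inheritParams generate_nir_set
#' @param grid MIR wavenumber grid.
#' @param n_replicates replicate count for the solution spectra (default 1;
#'   each solution is measured once with heavy scan co-addition).
#' @return list with `set` (an absorbance [spectra_set()]) and `truth`
#'   (with MIR band centers).
#' @export
generate_mir_set <- function(design, components = component_models(),
                             grid = mir_grid(), n_replicates = 1L) {
  .with_seed(design$seed, {
    rows <- list(); meta <- list(); k <- 0L
    for (l in seq_len(design$n_levels)) {
      for (r in seq_len(n_replicates)) {
        k <- k + 1L
        amounts <- c(casein = design$casein_levels[l],
                     nitrate = design$nitrate_levels[l],
                     water = 1.0, cellulose = 0)
        gain <- 1 + rnorm(1, 0, design$scatter_sd)
        base_coeffs <- rnorm(3, 0, design$baseline_sd)
        noise <- rnorm(length(grid), 0, design$noise_sd)
        rows[[k]] <- .assemble_abs(grid, components, amounts, "mir_bands",
                                   gain, base_coeffs, noise)
        meta[[k]] <- data.frame(
          sample_id = sprintf("solution_L%d_R%d", l, r),
          level_id = l, replicate_id = r, state = "solution",
          casein_conc = design$casein_levels[l],
          nitrate_conc = design$nitrate_levels[l],
          water_content = NA_real_)
      }
    }
    samples <- do.call(rbind, meta)
    set <- spectra_set(grid, do.call(rbind, rows), samples, "absorbance")
    truth <- .truth_record(grid, components, samples, 1)
    truth$band_centers <- lapply(components, function(cm) {
      b <- cm$mir_bands
      if (!nrow(b)) return(data.frame(center = numeric(0),
                                      index = integer(0)))
      data.frame(center = b$center,
                 index = vapply(b$center,
                                function(ct) which.min(abs(grid - ct)), 0L))
    })
    list(set = set, truth = truth)
  })
}

#' Generate a paired NIR leaf-model / MIR solution design
#'
#' One design drives both generators so `level_id i` carries identical
#' analyte concentrations in both sets — the alignment the hetero-spectral
#' two-dimensional correlation analysis relies on. The MIR set uses an
#' offset of the same seed so the two instruments' noise streams differ but
#' the pair stays reproducible.
#'
#' @inheritParams generate_nir_set
#' @return list with `nir` and `mir`, each a `list(set, truth)`.
#' @export
paired_design <- function(design, components = component_models()) {
  mir_design <- design
  mir_design$state <- "solution"
  mir_design$seed <- design$seed + 1000003L
  list(nir = generate_nir_set(design, components),
       mir = generate_mir_set(mir_design, components))
}
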