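# nirleaf

Simultaneous quantification of **proteinic** (casein) and **nitrate**
(nitric acid) nitrogen in filter-paper *leaf models* from near-infrared
diffuse-reflectance spectra.

NIR spectra of plant-like samples are dominated by water and matrix
overtone/combination bands; whole-spectrum regression against analyte
concentration picks up that interference. `nirleaf` implements a
band-selection calibration chain for this setting:

1. **Savitzky–Golay second derivatives** (2nd-order polynomial, 11-point
   NIR / 17-point MIR windows), working region 7500–4000 cm⁻¹;
2. **hetero-spectral generalized two-dimensional correlation
   spectroscopy** between the NIR leaf-model series and MIR spectra of the
   corresponding aqueous solutions, over the concentration-level
   perturbation: synchronous map `Φ = ÃᵀB̃/(m−1)`, asynchronous map
   `Ψ = ÃᵀNB̃/(m−1)` with `N` the Hilbert–Noda matrix;
3. **band selection**: per-wavenumber Pearson correlation of the second
   derivative with concentration, threshold `|r| ≥ 0.8`, intersection with
   the 2D hotspot indices (per five NIR analysis regions), wet/dry common
   bands, ±1-point band extension;
4. **PLS1 (NIPALS) calibration** with leave-one-out cross-validation,
   minimum-MAE factor selection, and the validation determination
   coefficient `R² = 1 − SSE/SST` of pooled LOO predictions.

A seeded synthetic generator (`generate_nir_set()`, `generate_mir_set()`,
`paired_design()`) emulates the study design — nine concentration levels,
six replicate acquisitions, wet/dry leaf models, solution MIR — as
Beer–Lambert mixtures of Gaussian component bands with known ground
truth, so every stage and the end-to-end recovery property are testable
without measured data.

## Worked example

```r
library(nirleaf)

cfg <- pipeline_config(seed = 1)       # study design, default settings
rep <- run_pipeline(cfg)
rep
#> <pipeline_report> seed 1
#>   casein_dry       109 band pts, 1 factor(s), LOO R2 = 0.999, MAE = 0.005461
#>   casein_wet       109 band pts, 3 factor(s), LOO R2 = 0.999, MAE = 0.005568
#>   nitrate_dry      60 band pts, 3 factor(s), LOO R2 = 1.000, MAE = 0.002129
#>   nitrate_wet      60 band pts, 3 factor(s), LOO R2 = 0.999, MAE = 0.003153

unlist(rep$band_recovery)              # fraction of true analyte band
#>  casein_dry  casein_wet nitrate_dry nitrate_wet      centers recovered
#>           1           1           1           1
```

Each line is one calibration scenario (analyte × leaf-model state): the
number of selected band points fed to PLS1, the cross-validated factor
count, and the leave-one-out validation R² and mean absolute error in %N.
`band_recovery = 1` means every true analyte band center planted by the
generator lies inside the selected bands.

The motivating contrast — band selection versus the full 7500–4000 cm⁻¹
spectrum under heavy wet-model interference:

```r
wcfg <- pipeline_config(design = high_interference_design(),
                        states = "wet", analytes = "casein",
                        common_wet_dry = FALSE, seed = 1)
run_pipeline(wcfg)$calibrations$casein_wet$r2_validation
#> [1] 0.9598498
baseline_fullspectrum_run(wcfg, "casein", "wet")$r2_validation
#> [1] 0.9470524
```

A thin command-line front end lives at `inst/cli/nirleaf.R`
(`generate`, `run-all`, `calibrate` subcommands; `--seed`, `--outdir`,
`--config FILE.yaml`).

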