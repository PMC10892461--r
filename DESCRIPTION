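Package: nirleaf
Title: Band-Selected NIR Calibration of Proteinic and Nitrate Nitrogen in
    Leaf Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simultaneous quantification of proteinic (casein) and nitrate
    (nitric acid) nitrogen in filter-paper leaf models from near-infrared
    diffuse-reflectance spectra. Implements Savitzky-Golay second-derivative
    preprocessing, generalized two-dimensional correlation spectroscopy
    (synchronous and asynchronous Hilbert-Noda maps, including hetero-spectral
    NIR x MIR analysis), correlation-threshold wavenumber band selection with
    wet/dry common-band intersection and one-point band extension, and PLS1
    (NIPALS) regression with leave-one-out cross-validation and minimum-MAE
    factor selection. Ships a seeded synthetic leaf-model spectra generator
    with known ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
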