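Package: nrpquant
Title: Digital Quantification for Nitrocellulose Redox Permanganometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the digital-quantification side of nitrocellulose redox
    permanganometry (NRP), a dot-blot assay of total reductive (antioxidant)
    capacity in which sample-reduced permanganate deposits brown MnO2 on a
    membrane, and of its spatial extension HistoNRP for tissue-slice prints.
    Provides membrane image import with inversion to a reductive-intensity
    scale, spot detection and background-corrected integrated-density
    measurement (disk/annulus and Gel-Analyzer-style lane profiles),
    calibration-curve fitting with bioanalytical validation verdicts
    (accuracy, precision, linearity, CV), ratiometric protein-content
    normalization with a dispersion-justification gate, bilateral
    mirror-symmetry difference maps with per-region intensity-distribution
    comparison ranked by distance to a trauma site, and a synthetic membrane
    phantom generator with exact ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
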