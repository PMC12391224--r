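Package: thermowell
Title: Processing and Heteroscedastic Analysis of Multi-Well Isothermal
    Microcalorimetry Thermograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for cell-metabolic heat measurements from multi-well
    isothermal microcalorimeters (48-well cartridges with per-column
    reference capsules). Reads plate layouts and per-well heat-flow traces,
    applies reference subtraction, loading-spike trimming, column-wise
    drift and baseline correction, and trapezoidal integration to obtain
    total heat per well and per cell; fits a one-way generalized
    least squares model with group-specific variances (Wald F-test),
    Games-Howell pairwise comparisons and a compact letter display; scales
    per-cell heat to tissue-level heat densities and computes media
    electron donor-to-acceptor ratios; and simulates full cartridges with
    known kinetic ground truth so every stage is testable without an
    instrument.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    nlme,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
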