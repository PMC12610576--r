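Package: pcdexr
Title: Moving-Blocker Scatter Correction for Photon-Counting Dual-Energy Radiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation and evaluation of scatter correction in
    photon-counting dual-energy chest radiography. Models a LucAl-style
    PMMA/aluminium chest phantom in three sizes, a 120 kVp tungsten-anode beam
    normalized to a target entrance air kerma, an energy-resolving CdTe
    photon-counting detector with two thresholds, and Monte Carlo Compton
    scatter transport. Implements the moving-blocker scatter estimator
    (shadow-centre sampling, cubic interpolation, Gaussian smoothing),
    per-bin scatter subtraction, weighted-log dual-energy subtraction, and
    the IEC 62220-2-1 style dual-energy contrast (DEC) and dual-energy
    subtraction efficiency (DSE) metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
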