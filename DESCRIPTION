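Package: e2edose
Title: End-to-End Geometric Accuracy Analysis for MR-Guided Radiotherapy
    Dose Delivery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the end-to-end (E2E) geometric accuracy of
    dose delivery on an MR-linac from dosimeter readouts. Provides a volumetric
    dose-grid data model with trilinear resampling and rigid transforms,
    a synthetic dual-cone head-phantom plan generator with known ground-truth
    displacements, polymer-gel (R2 relaxation rate) and radiochromic-film
    (net optical density) dosimeter simulation and conversion chains,
    rigid dose-to-readout registration by Hooke-Jeeves pattern search over a
    correlation-ratio similarity metric, global 3D gamma-index analysis with an
    exhaustive verification oracle, and session-level reporting of displacement
    vectors and reproducibility statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
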