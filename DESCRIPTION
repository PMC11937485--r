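Package: mvmdm
Title: Max-Voting Multidimensional CNN Ensemble for Wavelet-Domain MRI
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Binary classification of structural-MRI-like volumes from
    first-level Haar (db1) wavelet subbands. Each sagittal slice is
    decomposed into approximation and detail subbands (CA/CH/CV/CD); three
    subband-specific feature routes feed a 1D, a 2D, and a 3D convolutional
    network (per-slice diagonal-detail gradient-magnitude energies, the
    mean-fused horizontal-detail image, and the vertical-detail volume), and
    a max-voting ensemble fuses the three binary predictions. Includes a
    deterministic phantom-cohort generator with class-dependent edge
    contrast so the full pipeline is testable without clinical data, a
    compact CPU training engine, declarative architecture specifications
    with symbolic shape and parameter tracing, stratified k-fold and
    cross-cohort evaluation harnesses, and confusion-matrix metric
    reporting.
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
    Matrix,
    pracma,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
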