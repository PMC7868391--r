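Package: ratesi
Title: Electrical Source Imaging for Sparse Rat Cortical EEG Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward and inverse modelling tools for electrical source imaging
    (ESI) with sparse intracranial EEG montages in the rat, built around a
    12-electrode cortical system. Provides finite-element forward modelling on
    tetrahedral single-compartment head models with St. Venant dipole loads and
    a transfer-matrix lead-field scheme, four inverse solvers (LCMV and DICS
    beamformers, sLORETA and eLORETA weighted minimum-norm estimators),
    surrogate single-dipole benchmarking with error-distance and reliability
    maps across signal-to-noise levels, phantom-style model-mismatch
    localization experiments, a synthetic multi-subject auditory steady-state
    response (ASSR) generator, an evoked-response source-contrast pipeline, and
    non-parametric cluster-based permutation statistics in source space.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    signal,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
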