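Package: breathe4d
Title: Synthetic 4D CT, Respiratory Gating and Film Dosimetry for a Moving Target
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully synthetic desk-scale re-creation of a dynamic thorax
    phantom study of irregular breathing in lung stereotactic body
    radiotherapy. Generates regular and irregular breathing traces,
    simulates retrospective phase-binned 4D CT of a moving spherical
    target (including acquisition latency and mis-binning), reconstructs
    maximum and average intensity projections, auto-contours GTV/ITV/PTV
    geometry, simulates gated and nongated intensity-modulated delivery
    onto a film plane moving with the target, models radiochromic film
    response and its sensitometric calibration, and quantifies agreement
    between planned and delivered dose with a 2D gamma analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    tools,
    readr,
    ggplot2,
    rlang,
    jsonlite,
    yaml,
    RNifti,
    generics,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
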