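Package: cathtrack
Title: Closed-Loop Simulation of Prospective Slice Tracking for MR-Guided
    Catheterization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator and analysis library for prospective,
    parameter-free slice tracking of gadolinium-filled balloon catheters
    during MR-guided cardiac catheterization. Provides a digital phantom
    with saturation-dependent contrast and through-plane partial volume,
    a Calibration/Runtime tracking state machine with slice shifting and
    miss-revert logic, slice- and stack-based balloon segmentation
    (classical robust-threshold backend and a small trainable
    encoder-decoder network), a semi-artificial training-data generator
    based on anisotropic 2D Gaussian balloons, and the evaluation metrics
    (accuracy, sensitivity, specificity, contrast-to-noise stratification,
    mode-time fractions, switch correctness) used to assess tracking
    performance.
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
    RNifti,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
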