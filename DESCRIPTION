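Package: usmikb
Title: Quantitative Ultrasound Molecular Imaging of Microbubble Binding
    Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying targeted-microbubble contrast-enhanced
    ultrasound (ultrasound molecular imaging, USMI). Implements the
    first-pass binding (FPB) pharmacokinetic model -- a modified local
    density random walk bolus transport term plus a well-mixed accumulating
    bound-microbubble compartment -- and per-voxel nonlinear least-squares
    estimation of the microbubble binding rate constant from the first
    minute of the wash-in. Also provides the semi-quantitative
    late-enhancement and differential-targeted-enhancement readouts from
    destruction-replenishment protocols, plane-median/volume-mean parameter
    aggregation, nonparametric longitudinal case-control statistics with
    Benjamini-Hochberg correction, fold-change based responder
    classification, and a synthetic 4-D cohort generator for validating
    the full pipeline.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
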