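Package: sijfat
Title: Diagnostic Accuracy of Quantitative Sacroiliac-Joint Fat-Fraction MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating region-of-interest (ROI) proton density fat
    fraction (PDFF) measurements of the sacroiliac joints as a quantitative
    imaging biomarker for axial spondyloarthritis. Provides subject-level
    summary statistics over a 3-slice by 4-quadrant by 3-ROI measurement grid,
    five candidate definitions of a positive sacroiliac-joint MRI, cut-off
    sweeps with Youden-index selection, reader-averaged operating points,
    Mann-Whitney AUC with DeLong confidence intervals, two-reader intraclass
    correlation, group comparisons with Tukey post-hoc contrasts, and logistic
    association models for extensive fat deposition. A calibrated hierarchical
    cohort simulator emulates the statistical structure of a two-reader
    diagnostic study so the whole pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
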