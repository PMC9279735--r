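Package: rtflow
Title: Decision Support for Adaptive Radiotherapy from Daily 3D Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tracks the dose actually received by targets and organs at risk
    over a fractionated radiotherapy course from daily 3D setup images.
    Deformably registers the planning anatomy to each day's image with a
    multi-resolution optical-flow algorithm, maps the planned dose onto the
    deformed anatomy, computes day-of-treatment and projected-cumulative
    dose-volume histograms and the dosimetric parameters monitored for
    adaptive replanning (V95, Dmean, Dmax, D1cc), flags warning and
    adaptation threshold crossings, forecasts parameter trends up to four
    fractions ahead with a linear model, and reports deformable-registration
    confidence metrics. Includes a synthetic head-and-neck phantom course
    simulator with exact ground truth so the whole pipeline is testable
    without patient data, plus readers for DICOM-RT objects and a portable
    NIfTI+JSON fixture format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
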