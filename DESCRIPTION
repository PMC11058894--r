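Package: ea4dflow
Title: Transmitral E/A Ratio Quantification from 4D Flow Cardiovascular MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring the transmitral early (E) and late (A)
    diastolic inflow peaks and their ratio from time-resolved three-directional
    phase-contrast (4D Flow) cardiovascular MRI. Implements two semi-automated
    mitral-plane methods (maximum inflow velocity, MVvel, and inflow volume,
    MVflow, on a tracked, motion-corrected mitral annulus plane) and one
    automated left-ventricular method (maximum speed anywhere inside an LV
    mask, LVvel), together with velocity-aliasing (phase-wrap) correction,
    polynomial background-phase correction, normalized cross-correlation
    valve-plane tracking, and the agreement statistics used to compare such
    methods (ordinary least squares regression, Bland-Altman limits of
    agreement, paired t tests, Fisher r-to-z comparison of correlations).
    Includes a synthetic 4D cardiac inflow phantom with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    EBImage,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
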