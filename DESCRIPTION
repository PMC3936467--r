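Package: seedrsfc
Title: Seed-Based Resting-State fMRI Connectivity and Cross-Validated
    Relapse-Risk Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for seed-based resting-state functional
    connectivity analysis of amygdala-subdivision seeds (basolateral and
    corticomedial), from 4D BOLD volumes to Fisher-z connectivity maps,
    cluster-extent corrected group contrasts, and a leave-one-out
    cross-validated logistic classifier of clinical outcome from
    cluster-mean connectivity.  Includes quadratic detrending, hard
    discrete-Fourier bandpass filtering (0.01-0.1 Hz), motion, white-matter
    and cerebrospinal-fluid nuisance regression, mask-renormalised Gaussian
    spatial smoothing, Monte-Carlo calibration of cluster-size thresholds
    for family-wise error control, and a fully synthetic resting-BOLD
    cohort generator with known planted seed-to-target coupling so every
    stage is testable without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
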