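Package: zpdxscreen
Title: Chemosensitivity Analysis for Zebrafish Patient-Derived Xenografts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for zebrafish patient-derived xenograft (zPDX)
    drug-screening trials in colorectal cancer. Converts per-embryo stained
    tumor areas at two timepoints into equivalent-volume percent changes,
    fits a linear mixed-effects model with per-avatar random intercepts and
    treatment slopes, issues per-avatar drug-response calls from predicted
    confidence intervals, classifies responses with adapted RECIST
    thresholds, clusters avatars by their random-effect response profiles
    with a Hartigan-Wong k-means implementation, and tests patient-avatar
    concordance with a tie-corrected Kendall rank correlation. Includes a
    synthetic-cohort generator with known ground truth for parameter
    recovery and calibration studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    Matrix,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    emmeans,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
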