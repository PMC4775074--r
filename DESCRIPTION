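Package: urinmr
Title: Urinary 1H-NMR Metabolomics Workflow for Pain-Type Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested re-implementation of a urinary 1H-NMR metabolomics
    classification workflow for discriminating neuropathic from nociceptive
    pain. Provides fixed-width spectral bucketing with exclusion windows and
    total-area normalization, a from-scratch NIPALS latent-variable engine
    (PCA, PLS-DA, OPLS-DA) with Pareto scaling, stratified cross-validated
    Q2Y and label-permutation validation, covariance/correlation loadings
    diagnostics, a borderline-aware contingency-table evaluation layer with
    an exact two-sided Fisher test, and a synthetic urine-spectrum simulator
    so the whole pipeline is testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, readxl, withr, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
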