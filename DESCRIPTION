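Package: iecad
Title: Multi-Task Echocardiographic Video Analysis for Coronary Artery
    Disease Grading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for coronary artery disease (CAD) screening from
    echocardiographic video. Provides a synthetic beating-heart phantom
    generator with analytically known strain, ejection-fraction, myocardial
    work and Gensini-score labels; preprocessing of cardiac-cycle videos
    into fixed 20-frame blocks; deterministic clinical scoring (modified
    Gensini score, significant/severe CAD rules, biplane Simpson volumes,
    strain and work-efficiency curves); a multi-task 3D encoder-decoder
    network with low-rank expert feature fusion for view classification,
    cardiac segmentation, GLS/LVEF/GWE regression, Gensini-score regression
    and CAD classification, built on a self-contained reverse-mode
    autograd core; a three-phase training schedule; max-over-views study
    inference; and evaluation metrics with bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    mgcv,
    jsonlite,
    yaml,
    png,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
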