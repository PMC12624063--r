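Package: wmhgrade
Title: Automated Grading of White Matter Hyperintensities from Label Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream grading of white matter hyperintensities (WMH) on
    FLAIR-derived label volumes. Separates a WMH mask into periventricular
    (PVH) and deep/subcortical (DWMH) components with a spacing-aware 10 mm
    periventricular shell and a per-slice 60 percent overlap rule, computes
    brain-normalized volume ratios, learns grade-boundary thresholds from a
    graded cohort (kernel-density peak midpoints, Youden-index maximization
    over all grades or adjacent grades only), predicts Fazekas and Brain Dock
    grades, and evaluates grading agreement with boundary and multi-class
    accuracy, F1, mean absolute error, and Cohen's and Fleiss' kappa. Includes
    a synthetic phantom generator with known PVH/DWMH ground truth and a
    grade-conditional cohort simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
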