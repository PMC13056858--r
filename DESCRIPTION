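Package: maldiml
Title: Serum MALDI-TOF Peptidome Profiling and Interpretable Diagnostic Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible workbench for serum MALDI-TOF
    peptidome case/control studies. Provides spectrum preprocessing (total
    ion current normalization, Savitzky-Golay smoothing, adaptive iterative
    penalized-least-squares baseline correction), signal-to-noise peak
    detection with matrix-cluster exclusion, greedy cross-sample peak
    alignment at ppm tolerance, relative-peak-area feature matrices, a
    differential-peptide screen, an eight-family classifier benchmark with
    cross-validated ROC evaluation, Gini/SHAP/LIME feature importance with
    intersection-based core-feature selection, simplified-model rebuilds,
    single-marker ROC and decision-curve analysis, unsupervised clustering
    checks, peptide annotation utilities, and a fully seeded synthetic
    cohort generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    e1071,
    class,
    rpart,
    ranger,
    xgboost,
    kernlab,
    mclust,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mzR,
    withr
Config/testthat/edition: 3
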