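# maldiml

Serum MALDI-TOF peptidome profiling and interpretable diagnostic
modelling for case/control studies, in R.

Clinical peptidomics groups increasingly pair MALDI-TOF serum profiling
with machine learning to screen for cancers where single protein markers
are too weak — thyroid carcinoma being a canonical example: imaging lacks
specificity, and individual serum proteins rarely exceed AUC ~0.9 alone.
`maldiml` is a workbench for that study design. It takes profile-mode
spectra (one per patient) plus diagnosis labels, and carries them through:

1. **Preprocessing** — total-ion-current (TIC) normalization,
   Savitzky–Golay smoothing, and adaptive iterative baseline correction
   (airPLS-style asymmetric penalized least squares, compiled banded
   solver);
2. **Peak pipeline** — SNR-adaptive peak detection, exclusion of known
   matrix-cluster artifacts inside 1,500–2,000 Da, greedy cross-sample
   alignment of peaks into consensus bins within 2,500 ppm, and a samples
   × peaks matrix of relative peak areas (zero or interpolation fill);
3. **Differential screen** — per-bin log2 fold change, Welch's t on log
   areas, Benjamini–Hochberg q-values, top-k selectors;
4. **Classifier bench** — stratified 8:2 split and eight families (SVM,
   KNN, XGBoost, AdaBoost, leaf-wise LightGBM-style boosting, Gaussian
   naive Bayes, decision tree, random forest) with held-out AUC, accuracy,
   precision, recall, F1, average precision, and cross-validated ROC
   bands;
5. **Explainability** — Gini importance, exact TreeSHAP for the boosted
   trees plus sampling SHAP for the forest, LIME surrogates, and the
   SHAP ∩ LIME top-20 intersection that defines the core peptide panel;
6. **Diagnostic evaluation** — model rebuild on the core panel,
   single-marker ROC, decision-curve analysis
   (net benefit NB(pₜ) = TP/N − (FP/N)·pₜ/(1−pₜ) against treat-all /
   treat-none, with trapezoid areas), and an unsupervised check
   (bisecting k-means, BIRCH, ARI against diagnosis, 2-D embedding);
7. **Annotation** — parsing of annotated peptide tables
   (`R.MLLADQG….A`, `[P].TSAH….[P]`, bare), theoretical
   monoisotopic/average masses, ppm-tolerance matching of observed peaks;
8. **Synthetic cohorts** — a fully seeded generator (414 cases / 430
   controls by default, m/z 1,000–10,000, 12 planted discriminative peaks
   with |log2FC| ≥ 1 among 150 species, baseline drift, TIC variation,
   ppm mass drift, matrix artifacts) with ground truth, so every stage is
   testable without patient data.

Everything is data-frame-in / tibble-out and pipe-friendly, with
`autoplot()` methods and broom-style `tidy()`/`glance()` where a model
object is involved.

## Worked example

A reduced synthetic study (60 cases / 60 controls, everything else at the
default design) end to end:

```r
library(maldiml)

res <- run_pipeline(run_config(seed = 7, cohort = list(n_tc = 60, n_hc = 60)))

res$cohort
#> <maldi_cohort> 120 spectra (60 TC / 60 HC), 150 panel peaks (12 discriminative), 4 artifacts
res$bins
#> <peak_bins> 288 bins from 17654 peaks across 120 samples (tol 2500 ppm)

res$metrics[, c("family", "auc", "accuracy", "f1")]
#> # A tibble: 8 × 4
#>   family          auc accuracy    f1
#>   <chr>         <dbl>    <dbl> <dbl>
#> 1 adaboost          1        1     1
#> 2 decision_tree     1        1     1
#> 3 gaussian_nb       1        1     1
#> 4 knn               1        1     1
#> 5 lightgbm          1        1     1
#> 6 random_forest     1        1     1
#> 7 svm               1        1     1
#> 8 xgboost           1        1     1
```

The differential screen ranks the planted peptides first — the top rows
are all true positives, with fold changes close to the planted values:

```r
top_k_by_p(res$differential, 5)[, c("mz", "log2fc", "p_value", "q_value")]
#> # A tibble: 5 × 4
#>      mz log2fc  p_value  q_value
#>   <dbl>  <dbl>    <dbl>    <dbl>
#> 1 5905.   1.49 1.95e-56 3.28e-54
#> 2 5920.  -1.47 9.57e-54 8.04e-52
#> 3 1866.   1.36 7.27e-51 3.90e-49
#> 4 5354.  -1.19 9.29e-51 3.90e-49
#> 5 3242.  -1.26 6.07e-48 2.04e-46
```

The SHAP ∩ LIME intersection defines the core panel; here it captures all
12 planted discriminative peaks:

```r
res$core
#> <core_feature_set> 12 shared, 8 SHAP-unique, 8 LIME-unique (k = 20)
recovery_recall(res$core$shared, res$cohort$truth$discriminative_mz)
#> [1] 1
```

Decision-curve analysis of the simplified (core-panel) XGBoost model: at
prevalence 0.5 a perfect rule has net-benefit area 0.49 over the 0.01–0.99
threshold grid, and the rebuilt model is essentially there:

```r
glance(res$rebuild$dca$xgboost)
#> # A tibble: 1 × 4
#>    area area_all prevalence max_nb
#>   <dbl>    <dbl>      <dbl>  <dbl>
#> 1 0.482    -1.36        0.5    0.5
```

`autoplot()` works on spectra (with the fitted baseline overlaid),
decision curves, differential tables (volcano), and cluster results;
`plot_roc_curves(res$metrics)` draws the per-family test ROCs.

Real data enter the same way: `load_spectra()` reads a directory of
two-column CSVs or an mzML file, `read_sample_sheet()` supplies labels,
and the same stage functions (or `run_pipeline(cfg, cohort = )`) apply. A
thin command-line front end with `simulate`, `run-all`, `peaks`, and
`annotate` subcommands ships in `inst/scripts/maldiml.R`.

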