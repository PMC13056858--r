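---
title: "Serum peptidome diagnostics with maldiml: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum peptidome diagnostics with maldiml}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maldiml)
```

# The problem

Serum peptidome profiling by MALDI-TOF mass spectrometry produces, for each
patient, a profile-mode trace of intensity against m/z (here 1,000-10,000 Da,
the usual serum peptide window for singly charged ions). In a case/control
design — here thyroid carcinoma (TC) versus healthy controls (HC) — the
analysis task is to turn a few hundred such traces into (i) a samples x
peaks matrix of relative peak areas, (ii) a ranked list of differential
peptide peaks, (iii) a benchmarked diagnostic classifier, and (iv) a small,
interpretable core-feature panel whose clinical usefulness is judged by ROC
and decision-curve analysis rather than p-values alone.

`maldiml` implements that pipeline end to end, together with a synthetic
cohort generator with known ground truth, so every stage can be validated
without access to patient data.

# The synthetic cohort generator

`generate_cohort()` renders each sample as

$$ y(m) = s \left[ \sum_j a_j\, \mathcal N\!\big(m;\ \mu_j (1+\delta\,10^{-6}),\ \sigma_j\big) + b(m) \right] + \varepsilon(m), $$

clipped at zero, where the Gaussian is a density so each peak integrates to
its area $a_j$. The per-sample quantities are:

* $s$ — global intensity scale, log-normal with mean 1 and CV `tic_cv`
  (default 0.15), emulating spot-to-spot ionization variability;
* $\delta$ — mass-axis drift in ppm, Gaussian with SD `mass_drift_ppm_sd`
  (default 300 ppm), emulating calibration drift; well inside the 2,500 ppm
  alignment tolerance but large enough that naive grid-matching would fail;
* $a_j$ — log-normal around the species mean with biological CV `area_cv`
  (default 0.20); in cases the mean is multiplied by $2^{\mathrm{log2fc}_j}$;
* $b(m)$ — chemical background, by default $A e^{-(m - m_{low})/\tau}$ with
  $A = 20$, $\tau = 2000$ Da, mimicking matrix-cluster background that
  decays with mass;
* $\varepsilon$ — additive Gaussian noise (`noise_sd`, default 1), clipped
  with the signal at zero.

Peak widths default to $\sigma_j = 300\,\mathrm{ppm} \times \mu_j$,
a linear-TOF-like resolution. The default study design is 414 TC / 430 HC,
a 0.5 Da grid, and a panel of 150 species of which 12 are discriminative
with $|\mathrm{log2fc}| \ge 1$, planted at the core diagnostic m/z values
(1515.83, 1568.81, 1866.20, 2991.70, 3241.91, 3381.09, 3444.79, 3770.10,
5337.66, 5354.37, 5904.80, 5920.47) with alternating signs. Four
matrix-cluster artifact peaks are injected inside 1,500-2,000 Da, away from
the genuine peptides in that window. The filler species are placed by a
golden-ratio sequence on the log-m/z axis with at least 7,500 ppm pairwise
separation — deterministic, so the panel is a fixed object rather than a
random draw. The two closest planted pairs (5337.66/5354.37 at ~3,100 ppm
and 5904.80/5920.47 at ~2,650 ppm) deliberately sit just above the
alignment tolerance, exercising the one-peak-per-sample rule.

What the generator does *not* emulate: isotope envelopes, adducts, detector
saturation, replicate spots, batch effects, or heavy-tailed biological
variation. Passing the recovery tests therefore shows the pipeline is
internally consistent at realistic signal-to-noise, not that it will match
any particular instrument's quirks.

# Preprocessing

`preprocess()` applies, in order: TIC normalization to a common target
(default $10^4$), Savitzky-Golay smoothing, adaptive iterative baseline
correction, and (by default) a final re-normalization so that "relative
peak areas" are comparable across samples after background removal.

**Savitzky-Golay.** Defaults: window 11 points, order 3. On a 0.5 Da grid
an 11-point window spans 5.5 Da; wider windows (e.g. 21 points) visibly
crush low-mass peaks, whose physical width at 1,500 Da is only ~0.45 Da
(1.8 sigma per grid step), and in testing made the 1515.83/1568.81 species
undetectable. The filter reproduces polynomials up to its order exactly,
which the test suite asserts on random cubics.

**Baseline.** "Adaptive iterative" correction is implemented as
iteratively reweighted asymmetric penalized least squares (airPLS-style):
a Whittaker smoother with second-difference penalty $\lambda$ (default
$10^7$) is refit up to `max_iter` = 15 times, zeroing the weights of points
above the running baseline and anchoring the spectrum ends; convergence is
declared when the negative-residual mass falls below $10^{-3}$ of the total
signal. The pentadiagonal system is solved by a banded $LDL^T$
factorization in compiled code, $O(n)$ per iteration. With these defaults
the injected exponential background is recovered with RMSE < 5% of its
amplitude in peak-free regions. Negative residuals are clipped to zero so
areas stay non-negative.

**Numerical note on noise estimation.** Because clipping zeroes up to half
the points in signal-free regions, a plain sliding-window MAD collapses
toward zero there and inflates every SNR. The local noise estimator is
therefore the upper-quantile spread $(q_{75} - q_{50})/0.6745$, which
coincides with $1.4826 \times \mathrm{MAD}$ for Gaussian noise but remains
calibrated under left-censoring; detection additionally measures apex
height *above the local median level*, since the asymmetric baseline
estimate intentionally hugs the noise floor, leaving a small positive
offset in the corrected signal.

# Peak detection, artifact exclusion, and alignment

`detect_peaks()` keeps local maxima whose apex height above the local level
is at least `snr_min` (default 3) times the local noise; each peak's
centroid is the intensity-weighted mean over its half-height support and
its area the trapezoid integral over that support, with centroids closer
than one grid step merged.

`filter_matrix_clusters()` removes peaks that are both inside the
1,500-2,000 Da matrix-cluster region *and* within tolerance of a listed
artifact m/z. The region-restricted, list-matched rule (rather than blanket
removal) is deliberate: genuine serum peptides at 1515.83, 1568.81 and
1866.20 live in that window and must survive. On real data the artifact
list is supplied by the user (blank-spot runs, known matrix adducts); on
synthetic data it comes from the generator's ground truth.

`align_peaks()` groups the pooled peaks of all samples into consensus bins
within 2,500 ppm by an iterative greedy procedure: the unassigned peak with
the greatest support-weighted intensity (total unassigned area inside its
tolerance window) seeds a bin; each sample contributes at most its nearest
unassigned peak; consensus m/z is the area-weighted member mean; membership
is then refined against the consensus values until stable (at most 10
passes), with conflict losers falling back to their previous bin or a
singleton. A final cleanup evicts any member left outside tolerance by
consensus drift, so the "every member within 2,500 ppm of its consensus"
invariant is asserted, not hoped for. Because a seed-centred window spans
only ±tol while a well-placed consensus can cover members spanning up to
2×tol, a last merge pass joins neighbouring bins with disjoint samples
whenever the combined area-weighted consensus keeps every member within
tolerance — without it the greedy result can be provably non-minimal in
bin count. On instances small enough to
enumerate, the greedy partition matches an exhaustive branch-and-bound
search minimizing bin count (ties by centroid dispersion); the test suite
checks 100 such instances.

`build_feature_matrix()` fills cells for samples without a member peak by
zero (default) or by the mean of the sample's nearest flanking bins, and
records the imputation mask. Bins supported by fewer than `min_support`
of samples (pipeline default 0.25) are dropped; with the default design
this leaves ~150-160 bins, matching the planted panel, while uncorrelated
noise detections (support ~5%) disappear.

The differential screen uses Welch's t-test on log-transformed areas
(Mann-Whitney available by option) with Benjamini-Hochberg correction, and
log2 fold changes with a machine-scale pseudocount. A compositional caveat
is worth knowing: because TIC normalization forces each spectrum to a
common total, a planted fold change on species that carry a large share of
the total signal bleeds into apparent (opposite-sign) changes elsewhere. In
the default design the 12 planted species carry <15% of the signal, so the
distortion is small; users planting very dominant peaks should disable
re-normalization or interpret fold changes compositionally.

# The classifier bench

`stratified_split()` draws a per-class 80/20 partition (banker's rounding
per class), so the 414/430 design yields a test set of 83 + 86. The eight
families are SVM (RBF, e1071), k-nearest neighbours (k = 7, class), XGBoost
(depth-4 boosting), AdaBoost (SAMME over depth-2 rpart trees, implemented
in the package), a LightGBM-style leaf-wise histogram booster (31 leaves,
`grow_policy = "lossguide"` on the xgboost backend), Gaussian naive Bayes
(e1071), a decision tree (rpart), and a random forest (ranger, 500 trees).
SVM and KNN see z-scored features with means/SDs fitted on the training
rows only; tree families see raw areas. Every family exposes positive-class
probabilities (Platt scaling for the SVM, logistic mapping of the boosting
margin for AdaBoost).

Evaluation on the held-out test set reports AUC (tie-aware trapezoidal
empirical ROC, cross-checked against pROC in the tests), accuracy,
precision, recall, F1 and average precision, with the confusion matrix at
threshold 0.5 (ties positive). `crossval_roc()` adds stratified k-fold
variability on the training partition, interpolating fold ROCs on a common
grid and reporting mean +/- SD AUC. Under the default synthetic design the
signal is strong (per-feature effect size d around 3.5), and all families
sit at or near AUC 1.0 — by construction, features here lack the
correlation structure and batch noise of real cohorts, so the bench
separates "pipeline is wired correctly" from any claim about clinical
performance.

# Importance, SHAP/LIME intersection, and the core panel

Gini importance is read from the random forest and XGBoost (normalized to
sum 1 per model). SHAP values are exact tree-path attributions
(log-odds scale) for the two boosting families, and a seeded
permutation-sampling approximation (probability scale, 30 permutations,
up to 50 instances, background of up to 100 training rows) for the random
forest; each sampled permutation morphs one background row into the
explained instance, so per-instance attributions sum *exactly* to
$f(x) - \overline{f(b)}$. LIME fits a locality-weighted ridge surrogate on
1,000 Gaussian perturbations per instance (up to 100 test instances,
kernel width $0.75\sqrt p$), aggregating mean absolute weights.

Two design choices matter here, both made because sparse attribution under
strongly redundant signal otherwise hides true features:

* **Aggregation across model families is by mean of sum-normalized
  scores**, not mean rank. Boosted trees assign exactly zero SHAP to most
  of the 12 planted peaks (four or five of them suffice to separate the
  classes), and with ~140 features tied at zero, rank averaging buries
  features that another family ranks first. Score averaging keeps zeros
  neutral instead of punitive. Mean-rank aggregation remains available via
  `aggregate_importance(method = "mean_rank")`.
* **The SHAP default family set includes the random forest.** Forest
  randomization spreads credit across correlated/redundant informative
  features, complementing the concentrated boosting attributions.

`select_core_features()` takes the top-k (default 20) per method and
intersects them; the shared set is the core panel, and the Venn counts
(shared / SHAP-unique / LIME-unique) are reported. On the default design
the shared set recovers the planted 12 with mean recall of at least 0.9
over ten cohort replicates (asserted by the automated checks).

# Simplified model, single markers, decision curves, clustering

`rebuild_on_core()` retrains the bench on the shared features only, with
the same split and seeds — restriction to the full feature set reproduces
the full bench bit-for-bit, which the tests assert. `single_feature_auc()`
scores each core feature alone (orientation-corrected, ties handled by the
rank formula; equal to the normalized Mann-Whitney U, asserted against
`wilcox.test`). `dca_curve()` computes net benefit
$\mathrm{NB}(p_t) = \mathrm{TP}/N - (\mathrm{FP}/N)\, p_t/(1-p_t)$ on the
grid $p_t = 0.01, \dots, 0.99$ (step 0.01; $p_t = 1$ is excluded because
the weight diverges), against treat-all and treat-none references, and
integrates the *raw* curve by trapezoid — negative net benefit is not
clipped, so a harmful region genuinely lowers the reported area. At
prevalence ~0.49 a perfect classifier has area ~0.48; the 0.3-0.35 areas
typical of real cohorts reflect imperfect probabilities near the
high-threshold end.

The unsupervised check runs bisecting k-means (recursive 2-means splits of
the highest-variance cluster) and a BIRCH-style procedure (a single
clustering-feature pass with a distance threshold, then Ward merging of
subcluster centroids) on the standardized matrix, scoring agreement with
the diagnosis by adjusted Rand index. The 2-D embedding for visual
inspection uses the package's exact t-SNE (quadratic in n; perplexity
calibrated by bisection, early exaggeration, momentum gradient descent) or
PCA; t-SNE is the package's visualization choice for nonlinear structure
given the installed stack.

# Peptide annotation

`parse_annotation()` handles the three dialects found in identification
tables — bare sequences, dot-flanked (`R.SEQ.A`) and bracket-flanked
(`[P].SEQ.[P]`) — and validates residues. `peptide_mass()` sums standard
IUPAC residue masses (monoisotopic or average) plus water, optionally plus
a proton. Because observed MALDI masses in annotation tables mix
conventions and often deviate from theory by far more than instrument
accuracy, `match_observed()` tries all four mass conventions and gates on
ppm tolerance rather than asserting exact identity. The shipped example
panel (`example_peptide_panel()`) contains eleven annotated serum peptides;
one row's printed residue count (53, GRAMD1B) disagrees with its own
printed 49-residue sequence — the package reports what it parses and leaves
the table's internal inconsistency visible rather than silently correcting
either field.

# Problem sizes used by the automated checks

The test suite validates parameter recovery on the full default design
(414/430, ten replicate cohorts) for the core-recovery and tree-ensemble
AUC properties; null-behaviour properties (chance AUC, nominal BH false
discoveries over 20 replicates) run on a reduced 60/60, 1,000-4,000 Da
variant of the generator with all fold changes zero, a size at which those
properties are equally meaningful; and alignment-oracle equivalence runs
on 100 instances of up to 12 peaks, the largest size the exhaustive oracle
enumerates comfortably. The acceptance script executes one full-scale
end-to-end study plus a null control and writes every headline quantity it
computes to JSON.

# Known limitations

* The generator's Gaussian, isotope-free peaks and white noise make
  detection easier than on real linear-TOF traces; resolution-dependent
  asymmetry and detector saturation are not modelled.
* Sampling SHAP for non-tree families is Monte Carlo; with 30 permutations
  the per-feature ordering among near-tied weak features fluctuates
  (additivity, by contrast, is exact).
* The LightGBM family is the leaf-wise histogram growth strategy on the
  xgboost backend, not the LightGBM library; results will differ in detail
  from that implementation.
* With perfectly separable synthetic classes, probability calibration is
  extreme; decision-curve areas on real data will be lower and should be
  read on the test partition only.
* BIRCH is implemented as a single-pass CF absorption followed by Ward
  merging — adequate for cohort-scale n, but it is not the full CF-tree
  with node splitting.
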