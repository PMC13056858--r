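#' Rebuild the bench on the core feature set
#'
#' Restricts the feature matrix to the shared (SHAP intersect LIME) core
#' features, retrains every requested family on the same split, and
#' evaluates metrics and decision curves per family.
#'
#' @param fm The full `feature_matrix`.
#' @param core A `core_feature_set` (or character vector of feature names).
#' @param split The [stratified_split()] used for the full bench.
#' @param specs Model specs (default: all eight families).
#' @return A list of class `core_rebuild`: `bench`, `metrics`
#'   (test-partition [evaluate_classifiers()] rows), `dca` (named list of
#'   [dca_curve()]s per family).
#' @export
rebuild_on_core <- function(fm, core, split,
                            specs = default_model_specs()) {
  feats <- if (inherits(core, "core_feature_set")) core$shared else core
  if (length(feats) == 0) abort("core feature set is empty.")
  missing <- setdiff(feats, names(feature_mz(fm)))
  if (length(missing) > 0) {
    abort(paste0("unknown core features: ", paste(missing, collapse = ", ")))
  }
  keep <- c(intersect(c("sample_id", "label"), names(fm)), feats)
  sub <- fm[, keep]
  attr(sub, "bin_mz") <- feature_mz(fm)[feats]
  class(sub) <- class(fm)
  bench <- train_classifiers(sub, split, specs)
  metrics <- evaluate_classifiers(bench)
  probs <- attr(metrics, "probabilities")
  dca <- lapply(split(probs, probs$family), function(d) {
    dca_curve(d$prob, d$label)
  })
  structure(list(bench = bench, metrics = metrics, dca = dca),
            class = "core_rebuild")
}

#' Single-feature diagnostic AUC
#'
#' Empirical AUC of one feature used directly as a diagnostic score
#' (equivalently the normalized Mann-Whitney U). An AUC below 0.5 is
#' reported as `1 - AUC` with `flipped = TRUE`; a constant feature is
#' reported as 0.5 and flagged degenerate.
#'
#' @param values Feature values.
#' @param labels Class labels (`TC` positive).
#' @return Tibble row: `auc`, `flipped`, `degenerate`.
#' @export
single_feature_auc <- function(values, labels) {
  if (length(unique(labels)) < 2) abort("both classes must be present.")
  if (length(unique(values)) == 1) {
    return(tibble(auc = 0.5, flipped = FALSE, degenerate = TRUE))
  }
  a <- auc_score(values, labels)
  if (a < 0.5) tibble(auc = 1 - a, flipped = TRUE, degenerate = FALSE)
  else tibble(auc = a, flipped = FALSE, degenerate = FALSE)
}

#' Decision-curve analysis (net benefit)
#'
#' At each threshold probability `pt` the model predicts positive when the
#' predicted probability is at least `pt` (ties positive); the net benefit
#' is `NB(pt) = TP/N - (FP/N) * pt/(1-pt)`. Reference policies: treat-none
#' (`NB = 0`) and treat-all
#' (`NB = prevalence - (1 - prevalence) * pt/(1-pt)`). The curve's `area`
#' is the trapezoid integral of the raw (possibly negative) net benefit
#' over the threshold grid.
#'
#' @param probabilities Predicted positive-class probabilities in `[0, 1]`.
#' @param labels Class labels (`TC` positive).
#' @param thresholds Threshold grid in (0, 1); `pt = 1` is excluded by
#'   construction. Default `seq(0.01, 0.99, 0.01)`.
#' @return A tibble of class `dca_curve` (`threshold`, `nb`, `nb_all`,
#'   `nb_none`) with attributes `area`, `area_all`, `prevalence`.
#' @export
dca_curve <- function(probabilities, labels,
                      thresholds = seq(0.01, 0.99, by = 0.01)) {
  if (any(probabilities < 0 | probabilities > 1)) {
    abort("probabilities must lie in [0, 1].")
  }
  if (any(thresholds <= 0 | thresholds >= 1)) {
    abort("thresholds must lie strictly inside (0, 1).")
  }
  n <- length(labels)
  pos <- labels == .positive_class
  prev <- mean(pos)
  nb <- vapply(thresholds, function(pt) {
    pred <- probabilities >= pt
    (sum(pred & pos) - sum(pred & !pos) * pt / (1 - pt)) / n
  }, numeric(1))
  nb_all <- prev - (1 - prev) * thresholds / (1 - thresholds)
  out <- tibble(threshold = thresholds, nb = nb, nb_all = nb_all,
                nb_none = 0)
  attr(out, "area") <- trapezoid(thresholds, nb)
  attr(out, "area_all") <- trapezoid(thresholds, nb_all)
  attr(out, "prevalence") <- prev
  class(out) <- c("dca_curve", class(out))
  out
}

#' @export
print.dca_curve <- function(x, ...) {
  cat(sprintf("<dca_curve> %d thresholds, prevalence %.3f, area %.3f\n",
              nrow(x), attr(x, "prevalence"), attr(x, "area")))
  NextMethod()
}
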