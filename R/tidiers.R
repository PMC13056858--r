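#' Tidy the fitted bench: one row per model family
#' @param x A `maldi_bench`.
#' @param ... Unused.
#' @return Tibble (`family`, `seed`, `scaled`).
#' @export
tidy.maldi_bench <- function(x, ...) {
  tibble(family = names(x$models),
         seed = vapply(x$specs, function(s) s$seed, integer(1)),
         scaled = names(x$models) %in% .scaled_families)
}

#' One-row summary of a fitted bench
#' @param x A `maldi_bench`.
#' @param ... Unused.
#' @return Tibble (`n_models`, `n_features`, `n_train`, `n_test`).
#' @export
glance.maldi_bench <- function(x, ...) {
  tibble(n_models = length(x$models),
         n_features = length(x$feature_names),
         n_train = length(x$split$train_ids),
         n_test = length(x$split$test_ids))
}

#' Per-fold AUCs of a cross-validated ROC
#' @param x A [crossval_roc()] result.
#' @param ... Unused.
#' @export
tidy.crossval_roc <- function(x, ...) {
  tibble(fold = seq_along(x$fold_auc), auc = x$fold_auc)
}

#' One-row summary of a cross-validated ROC
#' @param x A [crossval_roc()] result.
#' @param ... Unused.
#' @export
glance.crossval_roc <- function(x, ...) {
  tibble(auc_mean = x$auc_mean, auc_sd = x$auc_sd, label = x$label)
}

#' Tidy a core feature set: membership of each top-listed feature
#' @param x A `core_feature_set`.
#' @param ... Unused.
#' @return Tibble (`feature`, `in_shap`, `in_lime`, `shared`).
#' @export
tidy.core_feature_set <- function(x, ...) {
  feats <- union(x$shap_top, x$lime_top)
  tibble(feature = feats,
         in_shap = feats %in% x$shap_top,
         in_lime = feats %in% x$lime_top,
         shared = feats %in% x$shared)
}

#' One-row summary of a decision curve
#' @param x A [dca_curve()].
#' @param ... Unused.
#' @return Tibble (`area`, `area_all`, `prevalence`, `max_nb`).
#' @export
glance.dca_curve <- function(x, ...) {
  tibble(area = attr(x, "area"), area_all = attr(x, "area_all"),
         prevalence = attr(x, "prevalence"), max_nb = max(x$nb))
}
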