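#' Gini (impurity-decrease) feature importance from tree ensembles
#'
#' Per-model impurity importances normalized to sum 1, for the tree
#' families of a bench (by default random forest and XGBoost, the two the
#' ensemble-importance step combines).
#'
#' @param bench A `maldi_bench`.
#' @param families Tree families to read importances from.
#' @return Importance tibble (`method`, `family`, `feature`, `score`);
#'   scores are non-negative and sum to 1 within each family.
#' @export
gini_importance <- function(bench,
                            families = c("random_forest", "xgboost")) {
  bad <- setdiff(families, .tree_families)
  if (length(bad) > 0) {
    abort(paste0("not a tree family: ", paste(bad, collapse = ", ")))
  }
  feats <- bench$feature_names
  rows <- lapply(families, function(fam) {
    m <- bench$models[[fam]]
    if (is.null(m)) abort(paste0("family not in bench: ", fam))
    imp <- setNames(rep(0, length(feats)), feats)
    if (fam == "random_forest") {
      vi <- m$fit$variable.importance
      imp[names(vi)] <- pmax(vi, 0)
    } else if (fam %in% c("xgboost", "lightgbm")) {
      it <- xgboost::xgb.importance(model = m$fit)
      imp[it$Feature] <- it$Gain
    } else if (fam == "decision_tree") {
      vi <- m$fit$variable.importance
      if (!is.null(vi)) imp[names(vi)] <- vi
    } else if (fam == "adaboost") {
      for (j in seq_along(m$fit$stumps)) {
        st <- m$fit$stumps[[j]]
        if (is.null(st)) next
        vi <- st$variable.importance
        if (!is.null(vi)) imp[names(vi)] <- imp[names(vi)] +
            m$fit$alphas[j] * vi
      }
    }
    if (sum(imp) > 0) imp <- imp / sum(imp)
    tibble(method = "gini", family = fam, feature = feats,
           score = unname(imp))
  })
  bind_rows(rows)
}

# margin-scale prediction for boosted-tree fits (log-odds)
xgb_margin <- function(fit, x) {
  predict(fit, xgboost::xgb.DMatrix(x, nthread = 1), outputmargin = TRUE)
}

#' SHAP feature attributions
#'
#' For boosted-tree families the exact tree-path (TreeSHAP) attributions on
#' the log-odds scale are used; attributions plus the bias term reproduce
#' the margin prediction to machine precision. For every other family a
#' seeded permutation-sampling approximation on the probability scale is
#' used: each sampled permutation walks one background row towards the
#' explained instance, so the per-instance attributions sum exactly to
#' `f(x) - mean(f(background))`.
#'
#' @param bench A `maldi_bench`.
#' @param families Families to explain (default: the two boosted-tree
#'   families, explained exactly, plus the random forest, explained by
#'   sampling).
#' @param eval_ids Sample ids to explain (default: test partition, capped
#'   at `max_eval`).
#' @param background_n Background rows (train partition) for the sampling
#'   approximation, capped at 100.
#' @param n_perm Sampled permutations per instance (sampling families).
#' @param max_eval Cap on explained instances.
#' @param seed Seed for the sampling approximation.
#' @return List of class `shap_result`: `table` (tibble `method`, `family`,
#'   `feature`, `score` = mean |SHAP|), `values` (per family, instances x
#'   features matrix), `expected` (per family baseline).
#' @export
shap_importance <- function(bench,
                            families = c("xgboost", "lightgbm",
                                         "random_forest"),
                            eval_ids = NULL, background_n = 100,
                            n_perm = 30, max_eval = 50, seed = 1L) {
  fm <- bench$fm
  x <- feature_values(fm)
  if (is.null(eval_ids)) {
    eval_ids <- head(bench$split$test_ids, max_eval)
  }
  xe_raw <- x[match(eval_ids, fm$sample_id), , drop = FALSE]
  bg_ids <- head(bench$split$train_ids, min(background_n, 100))
  if (length(bg_ids) == 0) abort("empty background set.")
  xb_raw <- x[match(bg_ids, fm$sample_id), , drop = FALSE]
  feats <- bench$feature_names
  values <- list(); expected <- list()
  for (fam in families) {
    m <- bench$models[[fam]]
    if (is.null(m)) abort(paste0("family not in bench: ", fam))
    scaled <- fam %in% .scaled_families
    xe <- if (scaled) bench$scale_fun(xe_raw) else xe_raw
    xb <- if (scaled) bench$scale_fun(xb_raw) else xb_raw
    if (fam %in% c("xgboost", "lightgbm")) {
      contrib <- predict(m$fit, xgboost::xgb.DMatrix(xe, nthread = 1),
                         predcontrib = TRUE)
      bias_col <- ncol(contrib)  # last column is the bias/intercept term
      values[[fam]] <- contrib[, feats, drop = FALSE]
      expected[[fam]] <- unname(contrib[1, bias_col])
    } else {
      res <- sampling_shap(m$predict_prob, xe, xb, n_perm = n_perm,
                           seed = seed)
      values[[fam]] <- res$values
      expected[[fam]] <- res$expected
    }
  }
  tbl <- bind_rows(lapply(names(values), function(fam) {
    tibble(method = "shap", family = fam, feature = feats,
           score = colMeans(abs(values[[fam]])))
  }))
  structure(list(table = tbl, values = values, expected = expected,
                 eval_ids = eval_ids),
            class = "shap_result")
}

# permutation-sampling Shapley values: for each sampled permutation a single
# background row is morphed feature-by-feature into the instance; the
# marginal prediction changes telescope, so per instance
# sum(phi) = f(x) - mean_r f(b_r) exactly. All of one instance's walks are
# stacked into a single prediction call.
sampling_shap <- function(predict_fun, xe, xb, n_perm = 30, seed = 1L) {
  p <- ncol(xe)
  phi <- matrix(0, nrow(xe), p, dimnames = list(NULL, colnames(xe)))
  f_bg <- numeric(nrow(xe))
  steps <- 0:p
  with_local_seed(seed, {
    for (i in seq_len(nrow(xe))) {
      perms <- replicate(n_perm, sample.int(p))
      bidx <- sample.int(nrow(xb), n_perm, replace = TRUE)
      blocks <- lapply(seq_len(n_perm), function(r) {
        rk <- integer(p); rk[perms[, r]] <- seq_len(p)
        M <- outer(steps, rk, ">=")          # (p+1) x p inclusion mask
        b <- matrix(xb[bidx[r], ], p + 1, p, byrow = TRUE)
        xm <- matrix(xe[i, ], p + 1, p, byrow = TRUE)
        b * (!M) + xm * M
      })
      big <- do.call(rbind, blocks)
      colnames(big) <- colnames(xe)
      f <- predict_fun(big)
      acc <- rep(0, p); base_sum <- 0
      for (r in seq_len(n_perm)) {
        seg <- f[((r - 1) * (p + 1) + 1):(r * (p + 1))]
        acc[perms[, r]] <- acc[perms[, r]] + diff(seg)
        base_sum <- base_sum + seg[1]
      }
      phi[i, ] <- acc / n_perm
      f_bg[i] <- base_sum / n_perm
    }
  })
  list(values = phi, expected = f_bg)
}

#' LIME local surrogate importance
#'
#' For each explained instance, fits a locality-weighted ridge regression
#' on seeded Gaussian perturbations (drawn around the instance with
#' train-fitted feature SDs) against the model's predicted probability; the
#' per-feature mean absolute surrogate weight over instances is the LIME
#' importance.
#'
#' @param bench A `maldi_bench`.
#' @param families Families to explain.
#' @param eval_ids Instances to explain (default test rows, capped).
#' @param n_perturb Perturbations per instance (>= 100).
#' @param max_eval Cap on explained instances (default 100).
#' @param kernel_width Locality kernel width in standardized distance units
#'   (default `0.75 * sqrt(p)`, the conventional choice).
#' @param ridge Ridge penalty of the surrogate.
#' @param seed Seed for the perturbation draws.
#' @return List of class `lime_result`: `table` (tibble `method`,
#'   `family`, `feature`, `score`).
#' @export
lime_importance <- function(bench, families = c("xgboost", "random_forest"),
                            eval_ids = NULL, n_perturb = 1000,
                            max_eval = 100, kernel_width = NULL,
                            ridge = 1e-3, seed = 1L) {
  if (n_perturb < 100) abort("n_perturb must be >= 100.")
  fm <- bench$fm
  x <- feature_values(fm)
  if (is.null(eval_ids)) eval_ids <- head(bench$split$test_ids, max_eval)
  xe <- x[match(eval_ids, fm$sample_id), , drop = FALSE]
  tr <- x[match(bench$split$train_ids, fm$sample_id), , drop = FALSE]
  sdv <- apply(tr, 2, sd); sdv[sdv == 0] <- 0  # zero-variance: no perturbation
  p <- ncol(x)
  if (is.null(kernel_width)) kernel_width <- 0.75 * sqrt(p)
  feats <- bench$feature_names
  tbl <- list()
  for (fam in families) {
    m <- bench$models[[fam]]
    if (is.null(m)) abort(paste0("family not in bench: ", fam))
    scaled <- fam %in% .scaled_families
    absw <- matrix(0, nrow(xe), p)
    with_local_seed(seed, {
      for (i in seq_len(nrow(xe))) {
        Z <- matrix(rnorm(n_perturb * p), n_perturb, p)
        X <- sweep(Z, 2, sdv, "*")
        X <- sweep(X, 2, xe[i, ], "+")
        colnames(X) <- feats
        xin <- if (scaled) bench$scale_fun(X) else X
        yhat <- m$predict_prob(xin)
        # locality weights in standardized space
        d2 <- rowSums(Z^2)
        wk <- exp(-d2 / kernel_width^2)
        # weighted ridge on standardized perturbation offsets
        sw <- sqrt(wk)
        Zs <- Z * sw
        ys <- (yhat - sum(wk * yhat) / sum(wk)) * sw
        A <- crossprod(Zs) + diag(ridge * n_perturb, p)
        beta <- solve(A, crossprod(Zs, ys))
        absw[i, ] <- abs(beta)
      }
    })
    tbl[[fam]] <- tibble(method = "lime", family = fam, feature = feats,
                         score = colMeans(absw))
  }
  structure(list(table = bind_rows(tbl)), class = "lime_result")
}

#' Aggregate an importance table across model families
#'
#' Per family the scores are normalized to sum 1, then averaged per feature
#' across families (`"mean_score"`, the default). `"mean_rank"` instead
#' averages within-family ranks (1 = most important); note that sparse
#' attribution methods tie many features at score 0, which makes rank
#' averages uninformative in the tail, so the score mean is the default.
#'
#' @param tbl Importance tibble (`method`, `family`, `feature`, `score`).
#' @param method `"mean_score"` or `"mean_rank"`.
#' @return Tibble (`feature`, `mean_rank`, `mean_score`) sorted by the
#'   chosen aggregate.
#' @export
aggregate_importance <- function(tbl,
                                 method = c("mean_score", "mean_rank")) {
  method <- match.arg(method)
  agg <- tbl |>
    group_by(.data$family) |>
    mutate(rank = rank(-.data$score, ties.method = "average"),
           norm_score = if (sum(.data$score) > 0) {
             .data$score / sum(.data$score)
           } else .data$score) |>
    ungroup() |>
    group_by(.data$feature) |>
    summarise(mean_rank = mean(.data$rank),
              mean_score = mean(.data$norm_score), .groups = "drop")
  if (method == "mean_score") {
    arrange(agg, desc(.data$mean_score), .data$mean_rank)
  } else {
    arrange(agg, .data$mean_rank, desc(.data$mean_score))
  }
}

#' Intersect the SHAP and LIME top-k lists into the core feature set
#'
#' @param shap_table,lime_table Importance tibbles (or the `shap_result` /
#'   `lime_result` objects).
#' @param k Top-list length per method (default 20; clipped with a warning
#'   when it exceeds the feature count).
#' @param aggregation Cross-family aggregation (see
#'   [aggregate_importance()]).
#' @return A list of class `core_feature_set`: `shap_top`, `lime_top`,
#'   `shared`, `shap_unique`, `lime_unique`, and the Venn counts in `venn`.
#' @export
select_core_features <- function(shap_table, lime_table, k = 20,
                                 aggregation = "mean_score") {
  if (inherits(shap_table, "shap_result")) shap_table <- shap_table$table
  if (inherits(lime_table, "lime_result")) lime_table <- lime_table$table
  feats <- union(shap_table$feature, lime_table$feature)
  if (!setequal(unique(shap_table$feature), unique(lime_table$feature))) {
    abort("SHAP and LIME tables must cover the same feature space.")
  }
  if (k > length(feats)) {
    warn(sprintf("k = %d exceeds the %d available features; clipping.",
                 k, length(feats)))
    k <- length(feats)
  }
  shap_top <- head(aggregate_importance(shap_table, aggregation)$feature, k)
  lime_top <- head(aggregate_importance(lime_table, aggregation)$feature, k)
  shared <- intersect(shap_top, lime_top)
  out <- list(shap_top = shap_top, lime_top = lime_top, shared = shared,
              shap_unique = setdiff(shap_top, shared),
              lime_unique = setdiff(lime_top, shared),
              k = k,
              venn = c(shared = length(shared),
                       shap_unique = length(setdiff(shap_top, shared)),
                       lime_unique = length(setdiff(lime_top, shared))))
  class(out) <- "core_feature_set"
  out
}

#' @export
print.core_feature_set <- function(x, ...) {
  cat(sprintf("<core_feature_set> %d shared, %d SHAP-unique, %d LIME-unique (k = %d)\n",
              x$venn["shared"], x$venn["shap_unique"], x$venn["lime_unique"],
              x$k))
  invisible(x)
}

#' Recall of planted discriminative peaks in a feature list
#'
#' @param features Character feature names (`mz_*`) or numeric m/z values.
#' @param truth_mz Planted discriminative m/z values.
#' @param tol_ppm Match tolerance.
#' @return Fraction of `truth_mz` matched by some feature within tolerance.
#' @export
recovery_recall <- function(features, truth_mz, tol_ppm = 2500) {
  if (is.character(features)) {
    features <- as.numeric(sub("^mz_", "", features))
  }
  if (length(truth_mz) == 0) return(NA_real_)
  mean(vapply(truth_mz, function(m) {
    any(abs(features - m) / m * 1e6 <= tol_ppm)
  }, logical(1)))
}
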