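#' Stratified train/test split
#'
#' Splits samples into train and test partitions, stratified by diagnosis
#' so both partitions preserve the class balance. The per-class test count
#' is `round((1 - train_frac) * n_class)` (banker's rounding).
#'
#' @param samples A tibble with `sample_id` and `label` columns (e.g.
#'   `cohort$samples` or a `feature_matrix`), or a bare label vector.
#' @param train_frac Fraction assigned to training (default 0.8).
#' @param seed Integer seed; the split is reproducible from it.
#' @return A list of class `split_indices`: `train_ids`, `test_ids`
#'   (sample ids, or integer indices for vector input), and `seed`.
#' @export
stratified_split <- function(samples, train_frac = 0.8, seed = 1L) {
  if (is.atomic(samples)) {
    samples <- tibble(sample_id = seq_along(samples),
                      label = as.character(samples))
  }
  if (train_frac <= 0 || train_frac >= 1) {
    abort("train_frac must be in (0, 1).")
  }
  classes <- unique(samples$label)
  if (any(table(samples$label) == 0) || length(classes) < 2) {
    abort("both classes must be present.")
  }
  with_local_seed(seed, {
    test_ids <- unlist(lapply(classes, function(cl) {
      ids <- samples$sample_id[samples$label == cl]
      n_test <- round((1 - train_frac) * length(ids))
      sample(ids, n_test)
    }), use.names = FALSE)
  })
  structure(list(train_ids = setdiff(samples$sample_id, test_ids),
                 test_ids = test_ids, seed = seed),
            class = "split_indices")
}

#' Classifier model specification
#'
#' @param family One of `"svm"`, `"knn"`, `"xgboost"`, `"adaboost"`,
#'   `"lightgbm"`, `"gaussian_nb"`, `"decision_tree"`, `"random_forest"`.
#'   The `"lightgbm"` family is a leaf-wise histogram gradient-boosting
#'   configuration (the LightGBM growth strategy) run on the xgboost
#'   backend.
#' @param params Named list of family hyperparameters overriding defaults.
#' @param seed Integer seed fixed into the fit.
#' @return A `model_spec` list.
#' @export
model_spec <- function(family, params = list(), seed = 1L) {
  family <- match.arg(family, c("svm", "knn", "xgboost", "adaboost",
                                "lightgbm", "gaussian_nb", "decision_tree",
                                "random_forest"))
  structure(list(family = family, params = params, seed = as.integer(seed)),
            class = "model_spec")
}

#' The eight-family default bench
#' @param seed Seed shared by every spec.
#' @return Named list of eight [model_spec()]s.
#' @export
default_model_specs <- function(seed = 1L) {
  fams <- c("svm", "knn", "xgboost", "adaboost", "lightgbm", "gaussian_nb",
            "decision_tree", "random_forest")
  setNames(lapply(fams, model_spec, seed = seed), fams)
}

# families whose inputs are standardized (scale-sensitive)
.scaled_families <- c("svm", "knn")
# tree-ensemble families (Gini importance, exact tree SHAP for boosted ones)
.tree_families <- c("xgboost", "lightgbm", "random_forest", "adaboost",
                    "decision_tree")

fit_one_family <- function(spec, x, y) {
  fam <- spec$family
  p <- spec$params
  yf <- factor(y, levels = c("HC", "TC"))
  y01 <- as.numeric(yf == "TC")
  get <- function(name, default) p[[name]] %||% default
  if (fam == "svm") {
    fit <- tryCatch(
      e1071::svm(x, yf, kernel = get("kernel", "radial"),
                 cost = get("cost", 1), probability = TRUE, scale = FALSE),
      error = function(e) NULL)
    if (!is.null(fit)) {
      pred_fun <- function(newx) {
        pr <- tryCatch({
          pp <- predict(fit, newx, probability = TRUE)
          attr(pp, "probabilities")[, "TC"]
        }, error = function(e) NULL)
        if (!is.null(pr)) return(unname(pr))
        dv <- attr(predict(fit, newx, decision.values = TRUE),
                   "decision.values")[, 1]
        flip <- if (grepl("^TC", colnames(attr(predict(fit, x[1, , drop = FALSE],
                  decision.values = TRUE), "decision.values"))[1])) 1 else -1
        plogis(flip * dv)
      }
    } else {  # fully degenerate input: constant score
      pred_fun <- function(newx) rep(mean(y01), nrow(newx))
    }
    return(list(fit = fit, predict_prob = pred_fun))
  }
  if (fam == "knn") {
    k <- get("k", 7)
    fit <- list(x = x, yf = yf, k = k)
    pred_fun <- function(newx) {
      pr <- class::knn(fit$x, newx, fit$yf, k = fit$k, prob = TRUE,
                       use.all = TRUE)
      w <- attr(pr, "prob")
      unname(ifelse(pr == "TC", w, 1 - w))
    }
    return(list(fit = fit, predict_prob = pred_fun))
  }
  if (fam %in% c("xgboost", "lightgbm")) {
    base <- list(objective = "binary:logistic", eta = get("eta", 0.1),
                 nthread = 1, seed = spec$seed)
    if (fam == "xgboost") {
      base <- c(base, list(max_depth = get("max_depth", 4),
                           subsample = get("subsample", 0.9),
                           colsample_bytree = get("colsample_bytree", 0.9)))
    } else {
      base <- c(base, list(tree_method = "hist", grow_policy = "lossguide",
                           max_depth = 0, max_leaves = get("max_leaves", 31),
                           subsample = get("subsample", 0.9),
                           colsample_bytree = get("colsample_bytree", 0.9)))
    }
    dtr <- xgboost::xgb.DMatrix(x, label = y01, nthread = 1)
    fit <- xgboost::xgb.train(params = base, data = dtr,
                              nrounds = get("nrounds", 150), verbose = 0)
    pred_fun <- function(newx) {
      predict(fit, xgboost::xgb.DMatrix(newx, nthread = 1))
    }
    return(list(fit = fit, predict_prob = pred_fun))
  }
  if (fam == "adaboost") {
    fit <- ada_fit(x, y, n_rounds = get("n_rounds", 80),
                   maxdepth = get("maxdepth", 2), seed = spec$seed)
    return(list(fit = fit, predict_prob = function(newx) predict(fit, newx)))
  }
  if (fam == "gaussian_nb") {
    fit <- e1071::naiveBayes(as.data.frame(x), yf)
    pred_fun <- function(newx) {
      pr <- predict(fit, as.data.frame(newx), type = "raw",
                    threshold = 0.001)
      unname(pr[, "TC"])
    }
    return(list(fit = fit, predict_prob = pred_fun))
  }
  if (fam == "decision_tree") {
    df <- as.data.frame(x); df$.y <- yf
    fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                        control = rpart::rpart.control(
                          cp = get("cp", 0.01), minsplit = get("minsplit", 4),
                          minbucket = get("minbucket", 2), xval = 0))
    pred_fun <- function(newx) {
      unname(predict(fit, as.data.frame(newx), type = "prob")[, "TC"])
    }
    return(list(fit = fit, predict_prob = pred_fun))
  }
  # random forest
  fit <- ranger::ranger(x = x, y = yf, probability = TRUE,
                        num.trees = get("num_trees", 500),
                        importance = "impurity", seed = spec$seed,
                        num.threads = 1)
  pred_fun <- function(newx) {
    unname(predict(fit, data = newx, num.threads = 1)$predictions[, "TC"])
  }
  list(fit = fit, predict_prob = pred_fun)
}

#' Train the classifier bench
#'
#' Fits one model per spec on the training rows only. Scale-sensitive
#' families (SVM, KNN) see features standardized with means/SDs fitted on
#' the training partition; tree families see raw relative areas. Every
#' family exposes probability predictions for the positive class (TC).
#'
#' @param fm A `feature_matrix` with labels.
#' @param split A [stratified_split()] result.
#' @param specs List of [model_spec()]s (default: all eight families).
#' @return A `maldi_bench` object holding the fitted models, the split and
#'   the train-fitted scaler.
#' @export
train_classifiers <- function(fm, split, specs = default_model_specs()) {
  x <- feature_values(fm)
  if (any(!is.finite(x))) abort("feature matrix contains non-finite values.")
  y <- setNames(fm$label, fm$sample_id)
  tr <- match(split$train_ids, fm$sample_id)
  if (anyNA(tr)) abort("split refers to unknown sample ids.")
  if (length(tr) < 2) abort("training partition needs at least 2 samples.")
  xtr <- x[tr, , drop = FALSE]; ytr <- y[tr]
  if (length(unique(ytr)) < 2) abort("training partition is single-class.")
  mu <- colMeans(xtr)
  sdv <- apply(xtr, 2, sd); sdv[sdv == 0] <- 1
  scale_fun <- function(m) sweep(sweep(m, 2, mu), 2, sdv, "/")
  models <- lapply(specs, function(sp) {
    xin <- if (sp$family %in% .scaled_families) scale_fun(xtr) else xtr
    with_local_seed(sp$seed, fit_one_family(sp, xin, ytr))
  })
  names(models) <- vapply(specs, function(sp) sp$family, character(1))
  structure(list(models = models, specs = specs, split = split,
                 scale_fun = scale_fun, feature_names = colnames(x),
                 fm = fm),
            class = "maldi_bench")
}

#' @export
print.maldi_bench <- function(x, ...) {
  cat(sprintf("<maldi_bench> %d fitted families (%s); train n=%d, test n=%d\n",
              length(x$models), paste(names(x$models), collapse = ", "),
              length(x$split$train_ids), length(x$split$test_ids)))
  invisible(x)
}

#' Predicted positive-class probabilities
#' @param bench A `maldi_bench`.
#' @param fm Feature matrix to score (default: the bench's own).
#' @param rows `"test"`, `"train"`, or `"all"`.
#' @return Tibble (`sample_id`, `label`, `family`, `prob`).
#' @export
bench_probabilities <- function(bench, fm = bench$fm,
                                rows = c("test", "train", "all")) {
  rows <- match.arg(rows)
  ids <- switch(rows, test = bench$split$test_ids,
                train = bench$split$train_ids, all = fm$sample_id)
  idx <- match(ids, fm$sample_id)
  x <- feature_values(fm)[idx, , drop = FALSE]
  lab <- fm$label[idx]
  bind_rows(imap(bench$models, function(m, fam) {
    xin <- if (fam %in% .scaled_families) bench$scale_fun(x) else x
    tibble(sample_id = ids, label = lab, family = fam,
           prob = as.numeric(m$predict_prob(xin)))
  }))
}

# ---- metrics ------------------------------------------------------------

#' Rank AUC (trapezoidal empirical ROC, tie-aware)
#' @param prob Scores (higher = more TC-like).
#' @param label Class labels (`TC` positive).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(prob, label) {
  pos <- label == .positive_class
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) abort("AUC needs both classes in the evaluation set.")
  r <- rank(prob)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision of the TC ranking
#' @inheritParams auc_score
#' @return Average precision in `[0, 1]`.
#' @export
average_precision <- function(prob, label) {
  o <- order(prob, decreasing = TRUE)
  pos <- (label == .positive_class)[o]
  if (sum(pos) == 0) return(0)
  prec_at <- cumsum(pos) / seq_along(pos)
  sum(prec_at[pos]) / sum(pos)
}

#' Empirical ROC points
#' @inheritParams auc_score
#' @return Tibble (`fpr`, `tpr`) stepping through score thresholds.
#' @export
roc_points <- function(prob, label) {
  o <- order(prob, decreasing = TRUE)
  pos <- (label == .positive_class)[o]
  # collapse ties on the score
  grp <- cumsum(!duplicated(prob[o]))
  tp <- cumsum(pos); fp <- cumsum(!pos)
  last <- !duplicated(grp, fromLast = TRUE)
  tibble(fpr = c(0, fp[last] / sum(!pos)), tpr = c(0, tp[last] / sum(pos)))
}

confusion_counts <- function(prob, label, threshold = 0.5) {
  pred_pos <- prob >= threshold
  pos <- label == .positive_class
  c(tp = sum(pred_pos & pos), fp = sum(pred_pos & !pos),
    fn = sum(!pred_pos & pos), tn = sum(!pred_pos & !pos))
}

metrics_from_scores <- function(prob, label, threshold = 0.5) {
  cc <- confusion_counts(prob, label, threshold)
  precision <- if (cc["tp"] + cc["fp"] > 0) cc["tp"] / (cc["tp"] + cc["fp"]) else 0
  recall <- if (cc["tp"] + cc["fn"] > 0) cc["tp"] / (cc["tp"] + cc["fn"]) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  tibble(auc = auc_score(prob, label),
         accuracy = unname((cc["tp"] + cc["tn"]) / sum(cc)),
         precision = unname(precision), recall = unname(recall),
         f1 = unname(f1),
         mean_average_precision = average_precision(prob, label))
}

#' Evaluate the bench on the held-out test partition
#'
#' Computes AUC (trapezoidal empirical ROC), accuracy, precision, recall,
#' F1 and average precision on the test rows only, with the confusion
#' matrix taken at probability threshold 0.5 (ties predicted positive).
#'
#' @param bench A trained `maldi_bench`.
#' @param fm Feature matrix (default: the bench's own).
#' @return Tibble of class `bench_metrics`, one row per family, with the
#'   per-family confusion counts (`tp`, `fp`, `fn`, `tn`) attached as
#'   columns and the raw test probabilities as attribute `probabilities`.
#' @export
evaluate_classifiers <- function(bench, fm = bench$fm) {
  probs <- bench_probabilities(bench, fm, rows = "test")
  if (length(unique(probs$label)) < 2) {
    abort("test partition is single-class; AUC undefined.")
  }
  out <- probs |>
    group_by(.data$family) |>
    summarise(metrics_from_scores(.data$prob, .data$label),
              as_tibble(as.list(confusion_counts(.data$prob, .data$label))),
              .groups = "drop")
  attr(out, "probabilities") <- probs
  class(out) <- c("bench_metrics", class(out))
  out
}

#' Cross-validated ROC for one family
#'
#' Stratified k-fold cross-validation on the training partition; each fold
#' is held out once, the mean ROC is interpolated on a common
#' false-positive-rate grid, and fold AUCs are summarised as mean and SD
#' (`"0.99 +/- 0.00"` style).
#'
#' @param spec A [model_spec()].
#' @param fm Feature matrix with labels.
#' @param split A [stratified_split()]; folds are drawn from its train ids.
#' @param k Number of folds (>= 2, at most the smallest class count).
#' @param seed Fold-assignment seed.
#' @return List of class `crossval_roc`: `mean_roc` (tibble `fpr`, `tpr`),
#'   `fold_auc`, `auc_mean`, `auc_sd`, `label`.
#' @export
crossval_roc <- function(spec, fm, split = NULL, k = 5, seed = 1L) {
  if (k < 2) abort("k must be >= 2.")
  ids <- if (is.null(split)) fm$sample_id else split$train_ids
  idx <- match(ids, fm$sample_id)
  x <- feature_values(fm)[idx, , drop = FALSE]
  y <- fm$label[idx]
  if (min(table(y)) < k) abort("k exceeds the smallest class count.")
  folds <- integer(length(y))
  with_local_seed(seed, {
    for (cl in unique(y)) {
      i <- which(y == cl)
      folds[i] <- sample(rep_len(seq_len(k), length(i)))
    }
  })
  grid <- seq(0, 1, by = 0.01)
  tprs <- matrix(NA_real_, k, length(grid))
  aucs <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    mu <- colMeans(x[tr, , drop = FALSE])
    sdv <- apply(x[tr, , drop = FALSE], 2, sd); sdv[sdv == 0] <- 1
    xin_tr <- x[tr, , drop = FALSE]; xin_te <- x[!tr, , drop = FALSE]
    if (spec$family %in% .scaled_families) {
      xin_tr <- sweep(sweep(xin_tr, 2, mu), 2, sdv, "/")
      xin_te <- sweep(sweep(xin_te, 2, mu), 2, sdv, "/")
    }
    m <- with_local_seed(spec$seed, fit_one_family(spec, xin_tr, y[tr]))
    pr <- m$predict_prob(xin_te)
    aucs[f] <- auc_score(pr, y[!tr])
    rp <- roc_points(pr, y[!tr])
    tprs[f, ] <- approx(rp$fpr, rp$tpr, xout = grid, ties = max, rule = 2)$y
  }
  structure(list(mean_roc = tibble(fpr = grid, tpr = colMeans(tprs)),
                 fold_auc = aucs, auc_mean = mean(aucs), auc_sd = sd(aucs),
                 label = sprintf("%.2f ± %.2f", mean(aucs), sd(aucs))),
            class = "crossval_roc")
}
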