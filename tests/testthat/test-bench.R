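test_that("stratified 8:2 split reproduces the per-class test counts", {
  labels <- tibble::tibble(
    sample_id = sprintf("S%03d", 1:844),
    label = rep(c("TC", "HC"), c(414, 430)))
  sp <- stratified_split(labels, seed = 3)
  test_lab <- labels$label[labels$sample_id %in% sp$test_ids]
  expect_length(sp$test_ids, 169)
  expect_equal(sum(test_lab == "TC"), 83)
  expect_equal(sum(test_lab == "HC"), 86)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_setequal(c(sp$train_ids, sp$test_ids), labels$sample_id)

  sp_small <- stratified_split(rep(c("TC", "HC"), each = 10), seed = 1)
  expect_length(sp_small$test_ids, 4)

  sp2 <- stratified_split(labels, seed = 3)
  expect_identical(sp$test_ids, sp2$test_ids)
  expect_error(stratified_split(rep("TC", 5)), "both classes")
})

test_that("every family separates a linearly separable toy set", {
  fm <- separable_fm()
  sp <- stratified_split(fm, train_frac = 0.8, seed = 2)
  bench <- train_classifiers(fm, sp)
  probs <- bench_probabilities(bench, rows = "train")
  acc <- probs |>
    dplyr::group_by(family) |>
    dplyr::summarise(acc = mean((prob >= 0.5) == (label == "TC")))
  expect_true(all(acc$acc == 1), info = paste(acc$family, acc$acc,
                                              collapse = "; "))
})

test_that("constant features give majority predictions and chance AUC", {
  x <- matrix(1, 40, 3)
  fm <- fm_from_matrix(x, rep(c("TC", "HC"), each = 20))
  sp <- stratified_split(fm, seed = 1)
  bench <- train_classifiers(fm, sp)
  met <- evaluate_classifiers(bench)
  expect_true(all(abs(met$auc - 0.5) <= 0.15))
  deterministic <- met$auc[met$family != "knn"]
  expect_true(all(deterministic == 0.5))
})

test_that("degenerate training inputs are rejected", {
  fm <- separable_fm()
  bad_split <- list(train_ids = fm$sample_id[1], test_ids = fm$sample_id[-1])
  expect_error(train_classifiers(fm, bad_split), "at least 2")
  fm_nf <- fm
  fm_nf[[3]][1] <- NA_real_
  expect_error(train_classifiers(fm_nf, stratified_split(fm, seed = 1)),
               "non-finite")
})

test_that("test metrics are perfect for perfect scores and degrade as expected", {
  lab <- rep(c("TC", "HC"), each = 25)
  perfect <- metrics_from_scores(ifelse(lab == "TC", 1, 0), lab)
  expect_true(all(abs(unlist(perfect) - 1) < 1e-12))

  allneg <- metrics_from_scores(rep(0.2, 50), lab)
  expect_equal(allneg$recall, 0)

  scores <- withr::with_seed(5, runif(2000))
  labels <- rep(c("TC", "HC"), 1000)
  expect_lt(abs(auc_score(scores, labels) - 0.5), 0.03)
})

test_that("AUC is tie-aware, monotone-invariant, and matches pROC", {
  skip_if_not_installed("pROC")
  for (seed in 1:5) {
    n <- 60
    dat <- withr::with_seed(seed, {
      list(score = round(runif(n), 2),
           label = sample(c("TC", "HC"), n, replace = TRUE))
    })
    a <- auc_score(dat$score, dat$label)
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = dat$label, predictor = dat$score,
      levels = c("HC", "TC"), direction = "<", quiet = TRUE)))
    expect_equal(a, ref, tolerance = 1e-12)
    expect_equal(auc_score(qlogis(dat$score / 1.001 + 1e-4), dat$label), a,
                 tolerance = 1e-12)
  }
  expect_error(auc_score(1:3, rep("TC", 3)), "both classes")
})

test_that("cross-validated ROC reports perfect separation as 1.00 +/- 0.00", {
  fm <- blob_fm(n_per = 25)
  sp <- stratified_split(fm, seed = 4)
  cv <- crossval_roc(model_spec("decision_tree"), fm, sp, k = 4, seed = 9)
  expect_equal(cv$auc_mean, 1)
  expect_equal(cv$auc_sd, 0)
  expect_match(cv$label, "1.00")
  expect_equal(max(cv$mean_roc$tpr), 1)
  expect_error(crossval_roc(model_spec("svm"), fm, sp, k = 1), "k must be")
  expect_error(crossval_roc(model_spec("svm"), fm, sp, k = 500),
               "smallest class")
  expect_equal(nrow(tidy(cv)), 4)
  expect_equal(glance(cv)$auc_mean, 1)
})

test_that("PCA explains a rank-2 structure exactly and is deterministic", {
  base <- withr::with_seed(8, matrix(rnorm(40 * 2), 40, 2))
  x <- base %*% matrix(c(1, 0.5, -1, 2, 0.3, 1), 2, 3)
  fm <- fm_from_matrix(x, rep(c("TC", "HC"), 20))
  rd <- reduce_dimensions(fm, "pca", dims = 2)
  ev <- attr(rd, "explained_variance")
  expect_equal(sum(ev[1:2]), 1, tolerance = 1e-9)
  rd2 <- reduce_dimensions(fm, "pca", dims = 2)
  expect_equal(abs(rd$dim1), abs(rd2$dim1))
  expect_error(reduce_dimensions(fm, "umap"), "arg")
})

test_that("planted class structure separates in 2-D projections", {
  fm <- blob_fm(n_per = 20, shift = 10)
  rd <- reduce_dimensions(fm, "pca", dims = 2)
  # mean silhouette of the diagnosis labels in the projected plane
  xy <- as.matrix(rd[, c("dim1", "dim2")])
  d <- as.matrix(dist(xy))
  sil <- vapply(seq_len(nrow(xy)), function(i) {
    own <- rd$label == rd$label[i]
    a <- mean(d[i, own & seq_len(nrow(xy)) != i])
    b <- mean(d[i, !own])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
  # kpca and t-SNE produce well-formed coordinates
  kp <- reduce_dimensions(fm, "kpca", dims = 2)
  expect_equal(dim(kp[, c("dim1", "dim2")]), c(40L, 2L))
  ts1 <- reduce_dimensions(fm, "tsne", dims = 2, seed = 3)
  ts2 <- reduce_dimensions(fm, "tsne", dims = 2, seed = 3)
  expect_identical(ts1$dim1, ts2$dim1)
})
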