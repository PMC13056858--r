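train_toy_bench <- function(fm, families = c("xgboost", "random_forest"),
                            seed = 1) {
  sp <- stratified_split(fm, seed = seed)
  specs <- lapply(families, model_spec, seed = seed)
  names(specs) <- families
  train_classifiers(fm, sp, specs)
}

test_that("Gini importance concentrates on the only informative feature", {
  x <- withr::with_seed(2, cbind(c(rnorm(20, 0, 0.2), rnorm(20, 3, 0.2)),
                                 rnorm(40)))
  fm <- fm_from_matrix(x, rep(c("HC", "TC"), each = 20))
  bench <- train_toy_bench(fm)
  gi <- gini_importance(bench)
  per_model <- tapply(gi$score, gi$family, sum)
  expect_true(all(abs(per_model - 1) < 1e-9))
  agg <- aggregate_importance(gi)
  expect_equal(agg$feature[1], names(feature_mz(fm))[1])
  f1 <- gi$score[gi$feature == names(feature_mz(fm))[1]]
  expect_true(all(f1 > 0.8))
  expect_error(gini_importance(bench, families = "svm"), "not a tree")
})

test_that("the stronger of two planted effects usually ranks first", {
  wins <- 0L
  for (seed in 1:50) {
    x <- withr::with_seed(seed, {
      cbind(c(rnorm(20, 0, 1), rnorm(20, 4, 1)),   # 4x the shift of f2
            c(rnorm(20, 0, 1), rnorm(20, 1, 1)),
            matrix(rnorm(40 * 3), 40, 3))
    })
    fm <- fm_from_matrix(x, rep(c("HC", "TC"), each = 20))
    sp <- list(train_ids = fm$sample_id, test_ids = fm$sample_id,
               seed = seed)
    bench <- train_classifiers(
      fm, sp, list(random_forest = model_spec(
        "random_forest", params = list(num_trees = 100), seed = seed)))
    gi <- gini_importance(bench, families = "random_forest")
    wins <- wins + (gi$feature[which.max(gi$score)] ==
                      names(feature_mz(fm))[1])
  }
  expect_gte(wins, 45)  # >= 90% of 50 seeded runs
})

test_that("TreeSHAP on a single stump attributes only the split feature", {
  x <- cbind(f_split = c(rep(0, 15), rep(1, 15)),
             f_noise = withr::with_seed(4, rnorm(30)))
  fm <- fm_from_matrix(x, rep(c("HC", "TC"), each = 15))
  sp <- list(train_ids = fm$sample_id, test_ids = fm$sample_id, seed = 1)
  spec <- model_spec("xgboost", params = list(max_depth = 1, nrounds = 1,
                                              eta = 1, subsample = 1,
                                              colsample_bytree = 1))
  bench <- train_classifiers(fm, sp, list(xgboost = spec))
  sh <- shap_importance(bench, families = "xgboost",
                        eval_ids = fm$sample_id)
  v <- sh$values$xgboost
  expect_true(all(abs(v[, 2]) < 1e-9))
  # the two leaves differ by the leaf-value gap, split evenly into the two
  # attribution groups
  gap <- diff(range(xgb_margin(bench$models$xgboost$fit,
                               feature_values(fm))))
  expect_equal(diff(range(v[, 1])), gap, tolerance = 1e-6)
})

test_that("TreeSHAP attributions satisfy local accuracy on the margin scale", {
  fm <- blob_fm(n_per = 25, p = 4, shift = 3)
  bench <- train_toy_bench(fm, families = c("xgboost", "lightgbm"))
  sh <- shap_importance(bench, families = c("xgboost", "lightgbm"),
                        eval_ids = fm$sample_id)
  for (fam in c("xgboost", "lightgbm")) {
    pred <- xgb_margin(bench$models[[fam]]$fit, feature_values(fm))
    recon <- rowSums(sh$values[[fam]]) + sh$expected[[fam]]
    # the tree backend evaluates in single precision
    expect_lt(max(abs(recon - pred)), 1e-5)
  }
})

test_that("sampling SHAP is additive by construction and zero for a constant model", {
  xe <- matrix(withr::with_seed(1, rnorm(10 * 3)), 10, 3,
               dimnames = list(NULL, c("a", "b", "c")))
  xb <- matrix(withr::with_seed(2, rnorm(30 * 3)), 30, 3,
               dimnames = list(NULL, c("a", "b", "c")))
  f_const <- function(m) rep(0.42, nrow(m))
  res <- maldiml:::sampling_shap(f_const, xe, xb, n_perm = 10, seed = 1)
  expect_true(all(res$values == 0))

  f_lin <- function(m) plogis(m[, 1] - 0.5 * m[, 3])
  res2 <- maldiml:::sampling_shap(f_lin, xe, xb, n_perm = 15, seed = 1)
  recon <- rowSums(res2$values) + res2$expected
  expect_lt(max(abs(recon - f_lin(xe))), 1e-10)
  # feature b carries no signal
  expect_lt(max(abs(res2$values[, 2])), 1e-10)
  res3 <- maldiml:::sampling_shap(f_lin, xe, xb, n_perm = 15, seed = 1)
  expect_identical(res2$values, res3$values)
})

test_that("LIME recovers a one-feature model and is seed-stable", {
  x <- withr::with_seed(6, {
    m <- matrix(rnorm(60 * 3), 60, 3)
    m[, 1] <- c(rnorm(30, 0, 0.5), rnorm(30, 4, 0.5))
    m
  })
  fm <- fm_from_matrix(x, rep(c("HC", "TC"), each = 30))
  bench <- train_toy_bench(fm, families = "xgboost")
  li <- lime_importance(bench, families = "xgboost", n_perturb = 500,
                        max_eval = 20, seed = 3)
  sc <- li$table$score
  expect_gt(sc[1] / sum(sc), 0.9)
  expect_lt(max(sc[2:3]), 0.05 * sc[1])
  li2 <- lime_importance(bench, families = "xgboost", n_perturb = 500,
                         max_eval = 20, seed = 3)
  expect_identical(li$table$score, li2$table$score)
  expect_error(lime_importance(bench, n_perturb = 50), "n_perturb")
})

test_that("core-feature selection obeys the Venn identities", {
  feats <- sprintf("mz_%d", 1:30)
  mk <- function(scores) tibble::tibble(method = "m", family = "f",
                                        feature = feats, score = scores)
  same <- select_core_features(mk(30:1), mk(30:1), k = 20)
  expect_length(same$shared, 20)
  expect_length(same$shap_unique, 0)

  disjoint <- select_core_features(mk(30:1), mk(1:30), k = 10)
  expect_length(disjoint$shared, 0)
  expect_length(disjoint$shap_unique, 10)

  partial <- select_core_features(mk(30:1),
                                  mk(c(15:1, 30:16)), k = 12)
  expect_equal(length(partial$shap_top),
               length(partial$shared) + length(partial$shap_unique))
  expect_equal(length(partial$lime_top),
               length(partial$shared) + length(partial$lime_unique))
  expect_length(intersect(partial$shap_unique, partial$shared), 0)

  expect_warning(out <- select_core_features(mk(30:1), mk(30:1), k = 50),
                 "clipping")
  expect_equal(out$k, 30)
  td <- tidy(same)
  expect_true(all(td$shared == (td$in_shap & td$in_lime)))
})

test_that("recovery recall matches within-tolerance counting", {
  expect_equal(recovery_recall(c("mz_1000.00", "mz_2000.00"),
                               c(1000.5, 2100)), 0.5)
  expect_equal(recovery_recall(c(1000, 2000), c(1000.5), tol_ppm = 100), 0)
  expect_true(is.na(recovery_recall(c(1000), numeric(0))))
})
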