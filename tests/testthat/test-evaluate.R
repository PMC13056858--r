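test_that("single-feature AUC handles orientation, ties and degeneracy", {
  expect_equal(single_feature_auc(c(1, 2, 3, 4),
                                  c("HC", "HC", "TC", "TC"))$auc, 1)
  r <- single_feature_auc(c(1, 3, 2, 4), c("HC", "HC", "TC", "TC"))
  expect_equal(r$auc, 0.75)
  expect_false(r$flipped)
  fl <- single_feature_auc(c(4, 3, 2, 1), c("HC", "HC", "TC", "TC"))
  expect_equal(fl$auc, 1)
  expect_true(fl$flipped)
  dg <- single_feature_auc(rep(2, 6), rep(c("TC", "HC"), 3))
  expect_equal(dg$auc, 0.5)
  expect_true(dg$degenerate)
  expect_error(single_feature_auc(1:3, rep("TC", 3)), "both classes")
})

test_that("single-feature AUC equals the normalized Mann-Whitney U statistic", {
  for (seed in 1:8) {
    dat <- withr::with_seed(seed, {
      n1 <- sample(5:25, 1); n0 <- sample(5:25, 1)
      list(v = c(rnorm(n1, 1), rnorm(n0)),
           lab = rep(c("TC", "HC"), c(n1, n0)), n1 = n1, n0 = n0)
    })
    u <- suppressWarnings(wilcox.test(dat$v[dat$lab == "TC"],
                                      dat$v[dat$lab == "HC"])$statistic)
    a <- auc_score(dat$v, dat$lab)
    expect_equal(a, unname(u) / (dat$n1 * dat$n0), tolerance = 1e-12)
  }
})

test_that("decision-curve identities hold on every grid point", {
  lab <- rep(c("TC", "HC"), c(30, 70))
  perfect <- dca_curve(ifelse(lab == "TC", 1, 0), lab)
  expect_true(all(abs(perfect$nb - 0.3) < 1e-12))
  expect_equal(attr(perfect, "area"), 0.3 * (0.99 - 0.01), tolerance = 1e-12)
  expect_true(all(perfect$nb_none == 0))
  prev <- attr(perfect, "prevalence")
  expect_equal(perfect$nb_all,
               prev - (1 - prev) * perfect$threshold / (1 - perfect$threshold),
               tolerance = 1e-12)

  # treat-all at pt = prevalence = 0.5 gives zero net benefit
  lab5 <- rep(c("TC", "HC"), 50)
  all_curve <- dca_curve(rep(1, 100), lab5)
  expect_equal(all_curve$nb[all_curve$threshold == 0.5], 0, tolerance = 1e-12)
  expect_equal(all_curve$nb, all_curve$nb_all, tolerance = 1e-12)

  expect_error(dca_curve(c(-0.1, 0.5), c("TC", "HC")), "probabilities")
  expect_error(dca_curve(c(0.1, 0.5), c("TC", "HC"), thresholds = c(0, 1)),
               "strictly inside")
})

test_that("trapezoid areas scale linearly in the integrand", {
  pt <- seq(0.01, 0.99, 0.01)
  nb <- sin(pt * 3) * 0.2
  expect_equal(trapezoid(pt, 5 * nb), 5 * trapezoid(pt, nb),
               tolerance = 1e-12)
})

test_that("a random classifier never beats treat-all below prevalence", {
  for (seed in 1:5) {
    dat <- withr::with_seed(seed, {
      list(p = runif(2000), lab = rep(c("TC", "HC"), c(980, 1020)))
    })
    d <- dca_curve(dat$p, dat$lab)
    prev <- attr(d, "prevalence")
    below <- d$threshold < prev - 0.02
    expect_true(all(d$nb[below] <= d$nb_all[below] + 0.02),
                label = paste("seed", seed))
  }
})

test_that("rebuilding on the full feature set reproduces the full bench", {
  fm <- blob_fm(n_per = 20, p = 6, shift = 4)
  sp <- stratified_split(fm, seed = 5)
  fams <- c("xgboost", "gaussian_nb", "decision_tree")
  specs <- setNames(lapply(fams, model_spec, seed = 11), fams)
  bench <- train_classifiers(fm, sp, specs)
  full_metrics <- evaluate_classifiers(bench)
  reb <- rebuild_on_core(fm, names(feature_mz(fm)), sp, specs)
  expect_equal(as.data.frame(reb$metrics), as.data.frame(full_metrics),
               tolerance = 1e-12)
  expect_named(reb$dca, sort(fams), ignore.order = TRUE)

  expect_error(rebuild_on_core(fm, "mz_9999.99", sp, specs), "unknown core")
  expect_error(rebuild_on_core(fm, character(0), sp, specs), "empty")
})

test_that("restricting to an informative core keeps held-out performance", {
  fm <- blob_fm(n_per = 30, p = 8, shift = 5)
  sp <- stratified_split(fm, seed = 2)
  specs <- list(xgboost = model_spec("xgboost", seed = 3))
  bench <- train_classifiers(fm, sp, specs)
  full_auc <- evaluate_classifiers(bench)$auc
  reb <- rebuild_on_core(fm, names(feature_mz(fm))[1:4], sp, specs)
  expect_lte(abs(reb$metrics$auc - full_auc), 0.05)
})
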