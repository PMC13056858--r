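test_that("a rendered Gaussian peak integrates to its area and shifts with drift", {
  g <- seq(2990, 3010, 0.5)
  sp <- generate_spectrum(peak_spec(3000, width_sd = 1.5,
                                    base_area_mean = 100), grid = g)
  expect_equal(trapezoid(sp$mz, sp$intensity), 100, tolerance = 0.1 / 100)

  g2 <- seq(2990, 3020, 0.5)
  sp2 <- generate_spectrum(peak_spec(3000, width_sd = 1.5,
                                     base_area_mean = 100),
                           grid = g2, drift_ppm = 1000)
  apex <- sp2$mz[which.max(sp2$intensity)]
  expect_lte(abs(apex - 3003), 0.5)

  empty <- generate_spectrum(peak_spec(numeric(0))[0, ], grid = g)
  expect_true(all(empty$intensity == 0))
})

test_that("generate_spectrum validates its inputs", {
  pan <- peak_spec(3000, base_area_mean = 10)
  expect_error(generate_spectrum(pan, grid = numeric(0)), "non-empty")
  expect_error(generate_spectrum(pan, grid = c(2, 1, 3)), "increasing")
  expect_error(generate_spectrum(pan, grid = 1:10, tic_scale = -1),
               "tic_scale")
  expect_error(generate_spectrum(pan, grid = 1:10, noise_sd = -1),
               "noise_sd")
})

test_that("cohorts have the requested composition and are seed-reproducible", {
  cfg <- narrow_config(n_tc = 10, n_hc = 10, seed = 5)
  coh <- generate_cohort(cfg)
  expect_length(coh$spectra, 20)
  expect_equal(sum(coh$samples$label == "TC"), 10)
  expect_identical(names(coh$spectra), coh$samples$sample_id)

  coh2 <- generate_cohort(cfg)
  expect_identical(coh$spectra[[3]]$intensity, coh2$spectra[[3]]$intensity)
  expect_identical(coh$truth$per_sample_drift_ppm,
                   coh2$truth$per_sample_drift_ppm)

  expect_error(generate_cohort(narrow_config(n_tc = 0, n_hc = 0)),
               "at least one sample")
})

test_that("config invariants are enforced", {
  expect_error(cohort_config(mz_range = c(5000, 1000)), "low < high")
  expect_error(cohort_config(grid_step = 0), "grid_step")
  expect_error(cohort_config(matrix_artifacts = c(1400)), "1500")
  expect_error(cohort_config(matrix_artifacts = c(2100)), "2000")
  expect_error(peak_spec(3000, prevalence = 0), "prevalence")
  # default artifacts all inside the matrix-cluster region
  cfg <- cohort_config()
  expect_true(all(cfg$matrix_artifacts >= 1500 &
                    cfg$matrix_artifacts <= 2000))
})

test_that("the realized TC/HC area ratio of a planted peak converges to 2^log2fc", {
  cfg <- narrow_config(n_tc = 200, n_hc = 200, seed = 9)
  coh <- generate_cohort(cfg)
  g <- coh$spectra[[1]]$mz
  win <- g > 2940 & g < 2960  # the planted fc = 1 peak at 2950
  area <- vapply(coh$spectra, function(s) {
    trapezoid(s$mz[win], s$intensity[win])
  }, numeric(1))
  is_tc <- coh$samples$label == "TC"
  ratio <- mean(area[is_tc]) / mean(area[!is_tc])
  # 3 standard errors of the ratio at CV 20% (plus 15% TIC CV), n = 200/arm
  se <- ratio * sqrt((0.2^2 + 0.15^2) / 200 * 2)
  expect_lt(abs(ratio - 2), 3 * se + 0.05)
})

test_that("default panel plants 12 discriminative peaks among ~150 species", {
  pan <- default_peak_panel()
  expect_equal(sum(pan$log2fc != 0), 12)
  expect_true(all(abs(pan$log2fc[pan$log2fc != 0]) >= 1))
  expect_equal(nrow(pan), 150)
  expect_true(all(diff(sort(pan$mz)) / pan$mz[-1] * 1e6 > 2500))
})
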