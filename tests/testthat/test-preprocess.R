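test_that("TIC normalization hits the target and preserves shape", {
  s <- spectrum_tbl(1:3, c(1, 2, 3))
  expect_equal(tic_normalize(s, 6)$intensity, c(1, 2, 3))
  s2 <- spectrum_tbl(1:3, c(2, 4, 6))
  expect_equal(tic_normalize(s2, 6)$intensity, c(1, 2, 3))
  expect_error(tic_normalize(spectrum_tbl(1:3, c(0, 0, 0)), 6), "all-zero")
})

test_that("TIC normalization is idempotent and commutes with scaling", {
  s <- spectrum_tbl(seq(1, 50), runif(50, 1, 5))
  once <- tic_normalize(s, 100)
  twice <- tic_normalize(once, 100)
  expect_equal(once$intensity, twice$intensity, tolerance = 1e-12)
  scaled <- spectrum_tbl(s$mz, s$intensity * 7.3)
  expect_equal(tic_normalize(scaled, 100)$intensity, once$intensity,
               tolerance = 1e-12)
})

test_that("Savitzky-Golay reproduces polynomials up to its order", {
  x <- seq_len(200)
  for (seed in 1:5) {
    cf <- withr::with_seed(seed, rnorm(4))
    y <- cf[1] + cf[2] * x / 100 + cf[3] * (x / 100)^2 + cf[4] * (x / 100)^3
    y <- y - min(y) + 1
    s <- spectrum_tbl(x, y)
    out <- smooth_savitzky_golay(s, window = 11, polyorder = 3, clip = FALSE)
    expect_equal(out$intensity, y, tolerance = 1e-9)
  }
  # quadratic with polyorder 2 and a different window
  yq <- (x / 10)^2
  expect_equal(smooth_savitzky_golay(spectrum_tbl(x, yq), 15, 2)$intensity,
               yq, tolerance = 1e-9)
})

test_that("order-0 SG behaves as a moving average on white noise", {
  w <- 11
  y <- withr::with_seed(1, rnorm(10000, mean = 50, sd = 2))
  s <- spectrum_tbl(seq_len(10000), y)
  out <- smooth_savitzky_golay(s, window = w, polyorder = 0)
  v <- var(out$intensity[500:9500] - 50)
  expect_lt(abs(v - 4 / w) / (4 / w), 0.2)
})

test_that("SG rejects invalid windows", {
  s <- spectrum_tbl(1:100, rep(1, 100))
  expect_error(smooth_savitzky_golay(s, window = 4), "odd")
  expect_error(smooth_savitzky_golay(s, window = 3, polyorder = 3),
               "exceed")
})

test_that("baseline correction recovers a constant offset exactly", {
  s <- spectrum_tbl(seq(1000, 2000, 0.5), rep(5, 2001))
  res <- correct_baseline(s)
  expect_lt(max(abs(attr(res$spectrum, "baseline") - 5)), 0.01 * 5)
  expect_lt(max(res$spectrum$intensity), 0.05)
  expect_true(res$fit$iterations_used <= 15)
})

test_that("baseline correction recovers an exponential baseline under peaks", {
  grid <- seq(1000, 6000, 0.5)
  true_bl <- 20 * exp(-(grid - 1000) / 1500)
  pan <- peak_spec(c(1800, 2500, 3300, 4100, 5200), base_area_mean = 120)
  sp <- generate_spectrum(pan, grid = grid)
  s <- spectrum_tbl(grid, sp$intensity + true_bl)
  res <- correct_baseline(s)
  est <- attr(res$spectrum, "baseline")
  peak_free <- rep(TRUE, length(grid))
  for (m in pan$mz) peak_free[abs(grid - m) < 8 * m * 300e-6] <- FALSE
  rmse <- sqrt(mean((est[peak_free] - true_bl[peak_free])^2))
  expect_lt(rmse, 0.05 * 20)
  # baseline never rides above the local minima envelope in peak-free zones
  expect_lt(max(est[peak_free] - s$intensity[peak_free]), 0.05 * 20)
})

test_that("degenerate baseline inputs error", {
  expect_error(spectrum_tbl(numeric(0), numeric(0)), "at least one point")
  s <- spectrum_tbl(1:10, c(1:9, NaN))
  expect_error(correct_baseline(s), "non-finite")
  expect_error(correct_baseline(spectrum_tbl(1:10, 1:10), lam = 0), "lam")
})

test_that("the preprocess composition renormalizes and stays non-negative", {
  coh <- small_cohort()
  pp <- small_cohort_pre()
  cfg <- preprocess_config()
  for (s in pp$spectra[1:4]) {
    expect_true(all(s$intensity >= 0))
    expect_equal(tic(s), cfg$target_tic, tolerance = 1e-6)
    expect_identical(spectrum_stage(s), "baseline_corrected")
  }
  bad <- spectrum_tbl(1:30, c(rep(1, 29), NA))
  expect_error(preprocess(bad), "non-finite")
})
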