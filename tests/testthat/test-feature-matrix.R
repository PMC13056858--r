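two_bin_setup <- function(drop_cell = TRUE) {
  # 3 samples x 3 species; sample s2 misses the middle species
  rows <- list()
  for (s in c("s1", "s2", "s3")) {
    for (j in 1:3) {
      if (drop_cell && s == "s2" && j == 2) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample_id = s, mz = c(2000, 3000, 4000)[j] + 0.01 * match(s, c("s1","s2","s3")),
        area = c(10, 20, 30)[j] + ifelse(s == "s2", 5, 0), snr = 10)
    }
  }
  align_peaks(dplyr::bind_rows(rows), tol_ppm = 2500)
}

test_that("zero and interpolation fill policies behave as specified", {
  bins <- two_bin_setup()
  fmz <- build_feature_matrix(bins, sample_ids = c("s1", "s2", "s3"),
                              fill = "zero")
  v <- feature_values(fmz)
  expect_equal(unname(v["s2", 2]), 0)
  expect_true(attr(fmz, "fill_mask")[2, 2])
  expect_equal(sum(attr(fmz, "fill_mask")), 1)

  fmi <- build_feature_matrix(bins, sample_ids = c("s1", "s2", "s3"),
                              fill = "interpolate")
  vi <- feature_values(fmi)
  expect_equal(unname(vi["s2", 2]), (15 + 35) / 2)  # mean of flanking areas

  # missing the first bin: interpolation falls back to 0 at the edge
  m2 <- bins$members[!(bins$members$sample_id == "s2" &
                         bins$members$bin_id == 1), ]
  bins2 <- bins; bins2$members <- m2
  bins2$bins$n_members[1] <- bins2$bins$n_members[1] - 1L
  fme <- build_feature_matrix(bins2, sample_ids = c("s1", "s2", "s3"),
                              fill = "interpolate")
  expect_equal(unname(feature_values(fme)["s2", 1]), 0)
})

test_that("row sums under zero fill never exceed total detected area", {
  coh <- small_cohort_pre()
  pk <- detect_peaks_all(coh)
  al <- align_peaks(pk)
  fm <- build_feature_matrix(al, sample_ids = coh$samples$sample_id,
                             labels = coh$samples, fill = "zero")
  rs <- rowSums(feature_values(fm))
  tot <- tapply(pk$area, pk$sample_id, sum)[fm$sample_id]
  expect_true(all(rs <= unname(tot) + 1e-9))
})

test_that("a duplicated sample inside a bin is rejected", {
  bins <- two_bin_setup(drop_cell = FALSE)
  bins$members$sample_id[2] <- "s1"  # corrupt: two s1 peaks in one bin
  expect_error(build_feature_matrix(bins), "more than one peak")
})

test_that("the differential screen finds planted effects and orders selectors", {
  cfg <- narrow_config(n_tc = 200, n_hc = 200, seed = 21)
  coh <- preprocess_all(generate_cohort(cfg))
  pk <- detect_peaks_all(coh)
  al <- align_peaks(pk)
  fm <- build_feature_matrix(al, sample_ids = coh$samples$sample_id,
                             labels = coh$samples, min_support = 0.5)
  dt <- differential_screen(fm)
  j <- which.min(abs(dt$mz - 2950))
  expect_lt(abs(dt$log2fc[j] - 1), 0.1)
  expect_lt(dt$q_value[j], 1e-6)
  null_fc <- dt$log2fc[abs(dt$mz - 2950) > 10]
  expect_true(all(abs(null_fc) < 0.2))

  topp <- top_k_by_p(dt, 2)
  expect_equal(nrow(topp), 2)
  expect_true(!is.unsorted(topp$p_value))
  topf <- top_k_by_abs_log2fc(dt, 2)
  expect_true(!is.unsorted(-abs(topf$log2fc)))
  expect_true(all(dt$q_value >= dt$p_value - 1e-12) && all(dt$q_value <= 1))
})

test_that("identical class means give zero log2fc and BH q-values are monotone", {
  x <- matrix(rep(c(5, 5, 5, 5), 6), 4, 6)
  x <- x + matrix(c(0.1, -0.1, 0.1, -0.1), 4, 6)
  fm <- fm_from_matrix(x, c("TC", "TC", "HC", "HC"))
  dt <- differential_screen(fm)
  expect_true(all(abs(dt$log2fc) < 1e-9))
  o <- order(dt$p_value)
  expect_true(!is.unsorted(dt$q_value[o]))

  fm_bad <- fm_from_matrix(x[1:3, ], c("TC", "HC", "HC"))
  expect_error(differential_screen(fm_bad), "at least 2")
})
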