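# shared fixtures, built in code; heavier objects are cached per test run
.fixture_env <- new.env(parent = emptyenv())

fixture_cache <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

# narrow-band cohort: one planted species (m/z 2950, a small share of the
# total signal so TIC closure barely shifts null features) among ten null
# species, no chemical baseline, fast to simulate
narrow_panel <- function(planted_log2fc = 1) {
  dplyr::bind_rows(
    peak_spec(2950, base_area_mean = 40, area_cv = 0.2,
              log2fc = planted_log2fc),
    peak_spec(seq(2610, 3390, by = 60), base_area_mean = 100,
              area_cv = 0.2))
}

narrow_config <- function(n_tc = 30, n_hc = 30, seed = 1,
                          planted_log2fc = 1, ...) {
  cohort_config(n_tc = n_tc, n_hc = n_hc, mz_range = c(2550, 3450),
                grid_step = 0.5, peak_panel = narrow_panel(planted_log2fc),
                baseline = NULL, noise_sd = 0.3,
                matrix_artifacts = numeric(0), seed = seed, ...)
}

# a small full-range cohort reused by several files
small_cohort <- function() {
  fixture_cache("small_cohort", function() {
    generate_cohort(cohort_config(n_tc = 8, n_hc = 8, seed = 42))
  })
}

small_cohort_pre <- function() {
  fixture_cache("small_cohort_pre", function() preprocess_all(small_cohort()))
}

# complete-null cohort on a reduced mass band (50 species, no class effect)
null_config <- function(seed) {
  mzs <- exp(seq(log(1100), log(3900), length.out = 50))
  areas <- 60 * 10^(((seq_along(mzs) * 0.618) %% 1) * 0.7)
  cohort_config(n_tc = 60, n_hc = 60, mz_range = c(1000, 4000),
                grid_step = 0.5,
                peak_panel = peak_spec(mzs, base_area_mean = areas,
                                       area_cv = 0.2),
                matrix_artifacts = c(1533.2, 1743.1),
                seed = seed)
}

# feature matrix built directly from a numeric matrix (bypasses spectra)
fm_from_matrix <- function(x, labels, mz = NULL) {
  if (is.null(mz)) mz <- 1000 + seq_len(ncol(x)) * 10
  cols <- sprintf("mz_%.2f", mz)
  colnames(x) <- cols
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("S%03d", seq_len(nrow(x))),
                   label = labels),
    tibble::as_tibble(x))
  attr(out, "bin_mz") <- stats::setNames(mz, cols)
  attr(out, "fill_mask") <- matrix(FALSE, nrow(x), ncol(x))
  class(out) <- c("feature_matrix", class(out))
  out
}

# two well-separated Gaussian blobs as a labelled feature matrix
blob_fm <- function(n_per = 20, p = 5, shift = 8, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per * p), n_per, p),
               matrix(rnorm(n_per * p, mean = shift), n_per, p))
  })
  fm_from_matrix(x, rep(c("HC", "TC"), each = n_per))
}

# linearly separable toy set (2 informative features)
separable_fm <- function(n_per = 10, seed = 7) {
  withr::with_seed(seed, {
    x <- cbind(c(rnorm(n_per, 0, 0.3), rnorm(n_per, 4, 0.3)),
               c(rnorm(n_per, 0, 0.3), rnorm(n_per, 4, 0.3)))
  })
  fm_from_matrix(x, rep(c("HC", "TC"), each = n_per))
}
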