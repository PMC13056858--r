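#' Peak panel specification
#'
#' One row per peptide species to plant in synthetic spectra. `log2fc` is the
#' planted case/control log2 fold change on the mean peak area; `prevalence`
#' is the fraction of samples in which the species is present at all.
#'
#' @param mz Peak centre (Da).
#' @param width_sd Gaussian sigma (Da); default 300 ppm of `mz`, mimicking
#'   linear-mode TOF resolution.
#' @param base_area_mean Mean integrated area in controls.
#' @param area_cv Biological coefficient of variation of the area
#'   (log-normal, so areas stay positive).
#' @param log2fc Planted log2 fold change (TC vs HC).
#' @param prevalence Fraction of samples carrying the peak, in (0, 1].
#' @return A tibble with one row per peak.
#' @export
peak_spec <- function(mz, width_sd = mz * 300e-6, base_area_mean = 100,
                      area_cv = 0.2, log2fc = 0, prevalence = 1) {
  out <- tibble(mz = mz, width_sd = width_sd,
                base_area_mean = base_area_mean, area_cv = area_cv,
                log2fc = log2fc, prevalence = prevalence)
  if (any(out$width_sd <= 0)) abort("width_sd must be > 0.")
  if (any(out$base_area_mean <= 0)) abort("base_area_mean must be > 0.")
  if (any(out$prevalence <= 0 | out$prevalence > 1)) {
    abort("prevalence must be in (0, 1].")
  }
  out
}

#' Baseline specification for synthetic spectra
#'
#' @param shape `"exponential_decay"` (`A * exp(-(mz - mz_low)/scale)`,
#'   mimicking matrix chemical background) or `"polynomial"`
#'   (`A * (1 - u)^degree` on the normalized m/z position `u`).
#' @param amplitude Baseline amplitude `A` at the low-mass edge.
#' @param scale Decay constant in Da (exponential shape).
#' @param degree Polynomial degree (polynomial shape).
#' @return A `baseline_spec` list.
#' @export
baseline_spec <- function(shape = c("exponential_decay", "polynomial"),
                          amplitude = 20, scale = 2000, degree = 3) {
  shape <- match.arg(shape)
  structure(list(shape = shape, amplitude = amplitude, scale = scale,
                 degree = degree),
            class = "baseline_spec")
}

baseline_values <- function(baseline, mz, mz_low = min(mz), mz_high = max(mz)) {
  if (is.null(baseline)) return(rep(0, length(mz)))
  switch(baseline$shape,
    exponential_decay = baseline$amplitude * exp(-(mz - mz_low) / baseline$scale),
    polynomial = {
      u <- (mz - mz_low) / (mz_high - mz_low)
      baseline$amplitude * (1 - u)^baseline$degree
    })
}

# low-discrepancy positions on a log-m/z axis (golden-ratio sequence),
# thinned to a minimum pairwise separation; deterministic by construction
.quasi_log_mz <- function(n, low, high, avoid = numeric(), min_sep_ppm = 7500) {
  phi <- (sqrt(5) - 1) / 2
  mzs <- numeric(0)
  k <- 1L
  while (length(mzs) < n && k < 20000L) {
    u <- (k * phi) %% 1
    cand <- low * exp(u * log(high / low))
    ok <- cand > low * 1.02 && cand < high * 0.98
    if (ok && length(c(mzs, avoid)) > 0) {
      sep <- abs(c(mzs, avoid) - cand) / cand * 1e6
      ok <- all(sep > min_sep_ppm)
    }
    if (ok) mzs <- c(mzs, cand)
    k <- k + 1L
  }
  sort(mzs)
}

#' Default synthetic serum peptidome panel
#'
#' Twelve discriminative peaks planted at the core diagnostic m/z values
#' (1515.83 ... 5920.47) with |log2fc| >= 1, plus `n_null` null species
#' spread quasi-randomly over the mass range, for roughly 150 aligned bins
#' downstream.
#'
#' @param n_null Number of non-discriminative filler peaks.
#' @param area_cv Biological CV applied to every peak.
#' @param mz_range Mass range (Da) the null peaks are spread over.
#' @return A peak panel tibble (see [peak_spec()]).
#' @export
default_peak_panel <- function(n_null = 138, area_cv = 0.2,
                               mz_range = c(1000, 10000)) {
  core_mz <- c(1515.83, 1568.81, 1866.20, 2991.70, 3241.91, 3381.09,
               3444.79, 3770.10, 5337.66, 5354.37, 5904.80, 5920.47)
  core_fc <- c(1.2, -1.1, 1.5, 1.0, -1.3, 1.1,
               -1.0, 1.4, 1.2, -1.2, 1.6, -1.5)
  core_area <- c(120, 90, 150, 110, 140, 100, 95, 130, 160, 120, 180, 150)
  null_mz <- .quasi_log_mz(n_null, mz_range[1], mz_range[2], avoid = core_mz)
  # deterministic area spread over roughly half an order of magnitude
  phi <- (sqrt(5) - 1) / 2
  null_area <- 40 * 10^(((seq_along(null_mz) * phi) %% 1) * 0.8)
  null_prev <- ifelse(seq_along(null_mz) %% 9 == 0, 0.8, 1)
  bind_rows(
    peak_spec(core_mz, base_area_mean = core_area, area_cv = area_cv,
              log2fc = core_fc),
    peak_spec(null_mz, base_area_mean = null_area, area_cv = area_cv,
              prevalence = null_prev)
  ) |> arrange(.data$mz)
}

#' Cohort configuration for the synthetic generator
#'
#' The defaults emulate a two-class serum MALDI-TOF study: 414 cases (TC)
#' and 430 controls (HC), spectra on a 0.5 Da grid over m/z 1000-10000,
#' exponential-decay chemical baseline, additive Gaussian noise, per-sample
#' multiplicative TIC variation, per-sample ppm-scale mass drift, and
#' matrix-cluster artifact peaks confined to the 1500-2000 Da region.
#'
#' @param n_tc,n_hc Number of case / control samples.
#' @param mz_range Mass range (low, high) in Da.
#' @param grid_step Grid spacing in Da.
#' @param peak_panel Peak panel tibble ([peak_spec()] rows).
#' @param baseline A [baseline_spec()], or `NULL` for no baseline.
#' @param noise_sd Additive Gaussian noise SD (intensity units).
#' @param tic_cv CV of the per-sample global intensity scale (log-normal).
#' @param mass_drift_ppm_sd SD of the per-sample relative mass-axis shift (ppm).
#' @param matrix_artifacts m/z values of matrix-cluster artifacts; all must
#'   lie within 1500-2000 Da.
#' @param artifact_area_mean,artifact_area_cv,artifact_prevalence Artifact
#'   peak intensity model (no class difference).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_tc = 414, n_hc = 430,
                          mz_range = c(1000, 10000), grid_step = 0.5,
                          peak_panel = default_peak_panel(mz_range = mz_range),
                          baseline = baseline_spec(),
                          noise_sd = 1, tic_cv = 0.15,
                          mass_drift_ppm_sd = 300,
                          matrix_artifacts = c(1533.2, 1610.5, 1743.1, 1925.4),
                          artifact_area_mean = 60, artifact_area_cv = 0.5,
                          artifact_prevalence = 0.9,
                          seed = 1L) {
  if (n_tc < 0 || n_hc < 0) abort("n_tc and n_hc must be >= 0.")
  if (mz_range[1] >= mz_range[2]) abort("mz_range must satisfy low < high.")
  if (grid_step <= 0) abort("grid_step must be > 0.")
  if (nrow(peak_panel) > 0 &&
      (any(peak_panel$mz <= mz_range[1]) || any(peak_panel$mz >= mz_range[2]))) {
    abort("all panel m/z must lie inside mz_range.")
  }
  if (length(matrix_artifacts) > 0 &&
      (any(matrix_artifacts < 1500) || any(matrix_artifacts > 2000))) {
    abort("matrix_artifacts must lie within [1500, 2000] Da.")
  }
  structure(list(n_tc = as.integer(n_tc), n_hc = as.integer(n_hc),
                 mz_range = mz_range, grid_step = grid_step,
                 peak_panel = peak_panel, baseline = baseline,
                 noise_sd = noise_sd, tic_cv = tic_cv,
                 mass_drift_ppm_sd = mass_drift_ppm_sd,
                 matrix_artifacts = matrix_artifacts,
                 artifact_area_mean = artifact_area_mean,
                 artifact_area_cv = artifact_area_cv,
                 artifact_prevalence = artifact_prevalence,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Render one synthetic profile-mode spectrum
#'
#' Intensity at each grid point is
#' `tic_scale * (sum_peaks area * N(mz; centre*(1+drift_ppm*1e-6), width_sd)
#'  + baseline(mz)) + noise`, clipped at zero. The Gaussian is a density, so
#' each peak integrates to its `area`.
#'
#' @param panel Peak panel tibble; `base_area_mean` is used as the realized
#'   area (draw biological variation upstream, e.g. in [generate_cohort()]).
#' @param baseline A [baseline_spec()] or `NULL`.
#' @param noise_sd Additive Gaussian noise SD (0 for noiseless).
#' @param drift_ppm Relative mass-axis shift in ppm.
#' @param tic_scale Global multiplicative intensity scale (> 0).
#' @param grid Strictly increasing m/z grid (Da).
#' @param sample_id Identifier for the resulting spectrum.
#' @param seed Optional seed for the noise draw; `NULL` uses the current RNG
#'   stream.
#' @return A [spectrum_tbl()] at stage `"raw"`.
#' @export
generate_spectrum <- function(panel, baseline = NULL, noise_sd = 0,
                              drift_ppm = 0, tic_scale = 1, grid,
                              sample_id = "sample", seed = NULL) {
  if (missing(grid) || length(grid) == 0) abort("grid must be non-empty.")
  if (is.unsorted(grid, strictly = TRUE)) {
    abort("grid must be strictly increasing.")
  }
  if (noise_sd < 0) abort("noise_sd must be >= 0.")
  if (tic_scale <= 0) abort("tic_scale must be > 0.")
  signal <- rep(0, length(grid))
  if (!is.null(panel) && nrow(panel) > 0) {
    centres <- panel$mz * (1 + drift_ppm * 1e-6)
    for (j in seq_len(nrow(panel))) {
      sdj <- panel$width_sd[j]
      i1 <- findInterval(centres[j] - 6 * sdj, grid) + 1L
      i2 <- findInterval(centres[j] + 6 * sdj, grid)
      if (i2 < i1) next
      idx <- i1:i2
      signal[idx] <- signal[idx] +
        panel$base_area_mean[j] * stats::dnorm(grid[idx], centres[j], sdj)
    }
  }
  signal <- signal + baseline_values(baseline, grid)
  draw <- function() {
    y <- tic_scale * signal
    if (noise_sd > 0) y <- y + rnorm(length(grid), 0, noise_sd)
    pmax(y, 0)
  }
  y <- if (is.null(seed)) draw() else with_local_seed(seed, draw())
  spectrum_tbl(grid, y, sample_id = sample_id, stage = "raw")
}

#' Generate a labelled synthetic cohort with ground truth
#'
#' Draws per-sample TIC scales (log-normal, mean 1), mass drifts
#' (Gaussian, ppm), per-peak biological areas (log-normal with the panel CV,
#' case means scaled by `2^log2fc`), peak presence (Bernoulli at the panel
#' prevalence), matrix artifact peaks, and additive noise. Identical
#' config + seed reproduces every spectrum exactly.
#'
#' @param config A [cohort_config()].
#' @return A list of class `maldi_cohort`: `spectra` (named list of
#'   [spectrum_tbl()]), `samples` (tibble `sample_id`, `label`), and `truth`
#'   (`discriminative_mz`, `artifact_mz`, `per_sample_drift_ppm`, plus the
#'   realized panel).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_tc + config$n_hc
  if (n == 0) abort("cohort must contain at least one sample.")
  grid <- seq(config$mz_range[1], config$mz_range[2], by = config$grid_step)
  labels <- rep(c("TC", "HC"), c(config$n_tc, config$n_hc))
  ids <- sprintf("S%04d_%s", seq_len(n), labels)
  panel <- config$peak_panel

  # static pieces shared by every sample
  base_vals <- baseline_values(config$baseline, grid)
  n_pan <- nrow(panel)
  n_art <- length(config$matrix_artifacts)
  pan_sdlog <- sqrt(log(1 + panel$area_cv^2))
  art_sdlog <- sqrt(log(1 + config$artifact_area_cv^2))
  art_sd <- config$matrix_artifacts * 300e-6
  npts <- length(grid)

  with_local_seed(config$seed, {
    drift <- rnorm(n, 0, config$mass_drift_ppm_sd)
    sdlog_t <- sqrt(log(1 + config$tic_cv^2))
    tic_scale <- rlnorm(n, meanlog = -sdlog_t^2 / 2, sdlog = sdlog_t)
    spectra <- vector("list", n)
    for (i in seq_len(n)) {
      if (n_pan > 0) {
        mean_i <- panel$base_area_mean *
          (if (labels[i] == "TC") 2^panel$log2fc else rep(1, n_pan))
        p_area <- rlnorm(n_pan, log(mean_i) - pan_sdlog^2 / 2, pan_sdlog)
        p_on <- runif(n_pan) <= panel$prevalence
      } else {
        p_area <- numeric(0); p_on <- logical(0)
      }
      if (n_art > 0) {
        a_area <- rlnorm(n_art,
                         log(config$artifact_area_mean) - art_sdlog^2 / 2,
                         art_sdlog)
        a_on <- runif(n_art) <= config$artifact_prevalence
      } else {
        a_area <- numeric(0); a_on <- logical(0)
      }
      mzs <- c(panel$mz[p_on], config$matrix_artifacts[a_on]) *
        (1 + drift[i] * 1e-6)
      sds <- c(panel$width_sd[p_on], art_sd[a_on])
      areas <- c(p_area[p_on], a_area[a_on])
      y <- base_vals
      for (j in seq_along(mzs)) {
        i1 <- findInterval(mzs[j] - 6 * sds[j], grid) + 1L
        i2 <- findInterval(mzs[j] + 6 * sds[j], grid)
        if (i2 < i1) next
        idx <- i1:i2
        y[idx] <- y[idx] + areas[j] * stats::dnorm(grid[idx], mzs[j], sds[j])
      }
      y <- tic_scale[i] * y
      if (config$noise_sd > 0) y <- y + rnorm(npts, 0, config$noise_sd)
      spectra[[i]] <- spectrum_tbl(grid, pmax(y, 0), sample_id = ids[i])
    }
    names(spectra) <- ids
    structure(list(
      spectra = spectra,
      samples = tibble(sample_id = ids, label = labels),
      truth = list(
        discriminative_mz = panel$mz[panel$log2fc != 0],
        discriminative_log2fc = panel$log2fc[panel$log2fc != 0],
        artifact_mz = config$matrix_artifacts,
        per_sample_drift_ppm = setNames(drift, ids),
        panel = panel),
      config = config),
      class = "maldi_cohort")
  })
}

#' @export
print.maldi_cohort <- function(x, ...) {
  cat(sprintf("<maldi_cohort> %d spectra (%d TC / %d HC), %d panel peaks (%d discriminative), %d artifacts\n",
              length(x$spectra), sum(x$samples$label == "TC"),
              sum(x$samples$label == "HC"), nrow(x$truth$panel),
              length(x$truth$discriminative_mz), length(x$truth$artifact_mz)))
  invisible(x)
}
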