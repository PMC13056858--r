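#' Local noise estimate
#'
#' Robust per-point noise level from the upper-quantile spread of the
#' intensity, `(q75 - median) / 0.6745`, evaluated in windows of width
#' `window_da` (block-wise, linearly interpolated between block centres).
#' For Gaussian noise this equals the usual 1.4826 x MAD estimator; unlike
#' the plain MAD it stays calibrated when baseline subtraction has clipped
#' a large share of the points to zero (the lower tail is censored but the
#' upper tail is intact). A window wider than the spectrum falls back to a
#' single global estimate.
#'
#' @param s A [spectrum_tbl()].
#' @param window_da Window width in Da (must exceed the grid step).
#' @return Numeric vector of per-point noise estimates.
#' @export
estimate_noise <- function(s, window_da = 200) {
  local_stats(s, window_da)$noise
}

# block-wise robust local level (median) and noise ((q75 - median)/0.6745),
# linearly interpolated between block centres
local_stats <- function(s, window_da = 200) {
  step <- if (nrow(s) > 1) min(diff(s$mz)) else 0
  if (window_da <= step) abort("window_da must exceed the grid step.")
  qstats <- function(x) {
    q <- unname(quantile(x, c(0.5, 0.75), names = FALSE, type = 7))
    c(level = q[1], noise = (q[2] - q[1]) / 0.6745)
  }
  span <- max(s$mz) - min(s$mz)
  if (window_da >= span || nrow(s) < 8) {
    q <- qstats(s$intensity)
    return(list(level = rep(q[["level"]], nrow(s)),
                noise = rep(q[["noise"]], nrow(s))))
  }
  n_block <- max(2L, ceiling(span / window_da))
  edges <- seq(min(s$mz), max(s$mz), length.out = n_block + 1)
  blk <- pmin(pmax(findInterval(s$mz, edges, rightmost.closed = TRUE), 1L),
              n_block)
  centres <- (edges[-1] + edges[-length(edges)]) / 2
  # m/z is sorted, so blocks are contiguous runs
  ends <- cumsum(tabulate(blk, n_block))
  starts <- c(1L, head(ends, -1) + 1L)
  present <- which(ends >= starts)
  blk_q <- vapply(present, function(b) {
    qstats(s$intensity[starts[b]:ends[b]])
  }, numeric(2))
  list(level = approx(centres[present], blk_q["level", ], xout = s$mz,
                      rule = 2)$y,
       noise = approx(centres[present], blk_q["noise", ], xout = s$mz,
                      rule = 2)$y)
}

trapezoid <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Adaptive-threshold peak detection
#'
#' Local maxima whose apex height above the local signal level (block-wise
#' median) is at least `snr_min` times the local noise estimate are kept. Each peak's centroid is the intensity-weighted
#' mean over its half-height support and its area the trapezoid integral
#' over that support; centroids closer than one grid step are merged
#' (largest area kept).
#'
#' @param s A preprocessed [spectrum_tbl()].
#' @param snr_min Minimum signal-to-noise ratio.
#' @param window_da Noise-estimation window (see [estimate_noise()]).
#' @return A tibble (`sample_id`, `mz`, `area`, `snr`) sorted by `mz`; empty
#'   when nothing is detected.
#' @export
detect_peaks <- function(s, snr_min = 3, window_da = 200) {
  assert_finite_spectrum(s)
  empty <- tibble(sample_id = character(), mz = numeric(),
                  area = numeric(), snr = numeric())
  y <- s$intensity
  n <- length(y)
  if (n < 3 || all(y == 0)) return(empty)
  st <- local_stats(s, window_da)
  noise <- pmax(st$noise, 1e-12)
  apex <- which(y[-c(1, n)] > y[-c(n - 1, n)] & y[-c(1, n)] >= y[-c(1, 2)]) + 1L
  if (length(apex) == 0) return(empty)
  # apex height above the local level, in local-noise units
  snr <- (y[apex] - pmax(st$level[apex], 0)) / noise[apex]
  keep <- snr >= snr_min & y[apex] > 0
  apex <- apex[keep]; snr <- snr[keep]
  if (length(apex) == 0) return(empty)
  bounds <- peak_support_cpp(y, apex)
  mz_c <- numeric(length(apex)); area <- numeric(length(apex))
  for (k in seq_along(apex)) {
    idx <- bounds[k, 1]:bounds[k, 2]
    w <- y[idx]
    mz_c[k] <- if (sum(w) > 0) sum(s$mz[idx] * w) / sum(w) else s$mz[apex[k]]
    area[k] <- if (length(idx) > 1) trapezoid(s$mz[idx], w) else w
  }
  o <- order(mz_c)
  mz_c <- mz_c[o]; area <- area[o]; snr <- snr[o]
  # merge centroids within one grid step: keep the largest area
  step <- min(diff(s$mz))
  if (length(mz_c) > 1) {
    grp <- cumsum(c(TRUE, diff(mz_c) > step))
    sel <- order(grp, -area)
    keep <- sort(sel[!duplicated(grp[sel])])
    mz_c <- mz_c[keep]; area <- area[keep]; snr <- snr[keep]
  }
  tibble(sample_id = sample_id(s), mz = mz_c, area = area, snr = snr)
}

#' Detect peaks in every spectrum of a cohort or list
#' @param spectra A `maldi_cohort` or list of spectra.
#' @inheritParams detect_peaks
#' @return One tibble of peaks with a `sample_id` column.
#' @export
detect_peaks_all <- function(spectra, snr_min = 3, window_da = 200) {
  sp <- if (inherits(spectra, "maldi_cohort")) spectra$spectra else spectra
  bind_rows(lapply(sp, detect_peaks, snr_min = snr_min,
                   window_da = window_da))
}

#' Exclude matrix-cluster artifact peaks
#'
#' Removes peaks that lie both inside the 1500-2000 Da matrix-cluster
#' region and within `tol_ppm` of a listed artifact m/z. Genuine peptide
#' peaks inside the region (not near a listed artifact) are retained.
#'
#' @param peaks Peak tibble from [detect_peaks()] / [detect_peaks_all()].
#' @param artifact_mzs Known artifact m/z values (possibly empty).
#' @param tol_ppm Match tolerance in ppm.
#' @param region Da interval of the matrix-cluster zone.
#' @return Filtered peak tibble.
#' @export
filter_matrix_clusters <- function(peaks, artifact_mzs, tol_ppm = 2500,
                                   region = c(1500, 2000)) {
  if (length(artifact_mzs) == 0 || nrow(peaks) == 0) return(peaks)
  in_region <- peaks$mz >= region[1] & peaks$mz <= region[2]
  near <- vapply(peaks$mz, function(m) {
    any(abs(m - artifact_mzs) / m * 1e6 <= tol_ppm)
  }, logical(1))
  peaks[!(in_region & near), , drop = FALSE]
}
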