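#' Total ion current normalization
#'
#' Rescales a spectrum so its summed intensity equals `target_tic`. Shape is
#' preserved up to the single scalar.
#'
#' @param s A [spectrum_tbl()].
#' @param target_tic Positive target total ion current.
#' @return The rescaled spectrum at stage `"normalized"`.
#' @export
tic_normalize <- function(s, target_tic = 1e4) {
  assert_finite_spectrum(s)
  if (target_tic <= 0) abort("target_tic must be > 0.")
  total <- tic(s)
  if (total <= 0) abort("cannot TIC-normalize an all-zero spectrum.")
  set_intensity(s, s$intensity * (target_tic / total), stage = "normalized")
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing (via [signal::sgolayfilt()]);
#' reproduces any polynomial up to degree `polyorder` exactly.
#'
#' @param s A [spectrum_tbl()].
#' @param window Odd filter length (points), `window > polyorder`.
#' @param polyorder Polynomial order of the local fit.
#' @param clip Clip negative filter output at zero (default TRUE).
#' @return Smoothed spectrum at stage `"smoothed"`.
#' @export
smooth_savitzky_golay <- function(s, window = 11, polyorder = 3, clip = TRUE) {
  assert_finite_spectrum(s)
  if (window %% 2 == 0) abort("window must be odd.")
  if (window <= polyorder) abort("window must exceed polyorder.")
  if (nrow(s) < window) abort("spectrum shorter than the filter window.")
  y <- signal::sgolayfilt(s$intensity, p = polyorder, n = window)
  if (clip) y <- pmax(y, 0)
  set_intensity(s, y, stage = "smoothed")
}

#' Adaptive iterative baseline correction
#'
#' Iteratively reweighted asymmetric penalized least squares (airPLS-style):
#' a Whittaker smoother with second-difference penalty `lam` is refit while
#' points above the running baseline are progressively excluded, so peaks do
#' not pull the baseline up. Stops when the mass of negative residuals falls
#' below `tol` of the total signal, or at `max_iter`.
#'
#' @param s A [spectrum_tbl()].
#' @param lam Smoothness penalty (> 0); larger gives a stiffer baseline.
#' @param max_iter Maximum reweighting iterations (>= 1).
#' @param tol Relative convergence tolerance on the negative-residual mass.
#' @return A list: `spectrum` (corrected, negatives clipped at 0, stage
#'   `"baseline_corrected"`) and `fit` (tibble row: `iterations_used`,
#'   `converged`) with the estimated `baseline` vector as attribute of the
#'   spectrum (`attr(, "baseline")`).
#' @export
correct_baseline <- function(s, lam = 1e7, max_iter = 15, tol = 1e-3) {
  assert_finite_spectrum(s)
  if (nrow(s) == 0) abort("zero-length spectrum.")
  if (lam <= 0) abort("lam must be > 0.")
  if (max_iter < 1) abort("max_iter must be >= 1.")
  res <- airpls_cpp(s$intensity, lam, as.integer(max_iter), tol)
  corrected <- pmax(s$intensity - res$baseline, 0)
  out <- set_intensity(s, corrected, stage = "baseline_corrected")
  attr(out, "baseline") <- as.numeric(res$baseline)
  list(spectrum = out,
       fit = tibble(sample_id = sample_id(s),
                    iterations_used = res$iterations,
                    converged = res$converged))
}

#' Preprocessing configuration
#'
#' @param target_tic Target total ion current for normalization.
#' @param sg_window,sg_polyorder Savitzky-Golay window and order.
#' @param baseline_lambda,baseline_max_iter,baseline_tol Baseline-correction
#'   parameters (see [correct_baseline()]).
#' @param renormalize Re-apply TIC normalization after baseline subtraction
#'   so relative peak areas are comparable across samples (default TRUE).
#' @return A named list of preprocessing parameters.
#' @export
preprocess_config <- function(target_tic = 1e4, sg_window = 11,
                              sg_polyorder = 3, baseline_lambda = 1e7,
                              baseline_max_iter = 15, baseline_tol = 1e-3,
                              renormalize = TRUE) {
  list(target_tic = target_tic, sg_window = sg_window,
       sg_polyorder = sg_polyorder, baseline_lambda = baseline_lambda,
       baseline_max_iter = baseline_max_iter, baseline_tol = baseline_tol,
       renormalize = renormalize)
}

#' Full spectrum preprocessing
#'
#' Applies, in order: TIC normalization, Savitzky-Golay smoothing, adaptive
#' iterative baseline correction, and (optionally) a final re-normalization,
#' recording stage provenance.
#'
#' @param s A raw [spectrum_tbl()].
#' @param cfg A [preprocess_config()].
#' @return The preprocessed spectrum.
#' @export
preprocess <- function(s, cfg = preprocess_config()) {
  assert_finite_spectrum(s)
  s |>
    tic_normalize(cfg$target_tic) |>
    smooth_savitzky_golay(cfg$sg_window, cfg$sg_polyorder) |>
    (\(x) correct_baseline(x, cfg$baseline_lambda, cfg$baseline_max_iter,
                           cfg$baseline_tol)$spectrum)() |>
    (\(x) if (isTRUE(cfg$renormalize) && tic(x) > 0) {
      out <- set_intensity(x, x$intensity * (cfg$target_tic / tic(x)),
                           stage = "baseline_corrected")
      attr(out, "baseline") <- attr(x, "baseline")
      out
    } else x)()
}

#' Preprocess every spectrum of a cohort or list
#' @param spectra A `maldi_cohort` or list of spectra.
#' @param cfg A [preprocess_config()].
#' @return List of preprocessed spectra (cohort input returns the cohort
#'   with spectra replaced).
#' @export
preprocess_all <- function(spectra, cfg = preprocess_config()) {
  if (inherits(spectra, "maldi_cohort")) {
    spectra$spectra <- lapply(spectra$spectra, preprocess, cfg = cfg)
    return(spectra)
  }
  lapply(spectra, preprocess, cfg = cfg)
}
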