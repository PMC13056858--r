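#' Construct a mass spectrum
#'
#' A spectrum is a tibble with columns `mz` (strictly increasing, Da) and
#' `intensity` (non-negative), carrying `sample_id` and a processing-stage
#' provenance tag as attributes.
#'
#' @param mz Numeric vector of m/z values (Da), strictly increasing.
#' @param intensity Numeric vector of intensities, same length as `mz`.
#' @param sample_id Sample identifier.
#' @param stage Provenance tag: one of `"raw"`, `"normalized"`, `"smoothed"`,
#'   `"baseline_corrected"`.
#' @return A tibble of class `maldi_spectrum`.
#' @examples
#' s <- spectrum_tbl(seq(1000, 1010, 0.5), rep(1, 21), "s1")
#' tic(s)
#' @export
spectrum_tbl <- function(mz, intensity, sample_id = "sample",
                         stage = c("raw", "normalized", "smoothed",
                                   "baseline_corrected")) {
  stage <- match.arg(stage)
  if (length(mz) != length(intensity)) {
    abort("`mz` and `intensity` must have the same length.")
  }
  if (length(mz) == 0) abort("spectrum must contain at least one point.")
  if (any(!is.finite(mz)) || is.unsorted(mz, strictly = TRUE)) {
    abort("`mz` must be finite and strictly increasing.")
  }
  out <- tibble(mz = as.numeric(mz), intensity = as.numeric(intensity))
  attr(out, "sample_id") <- as.character(sample_id)
  attr(out, "stage") <- stage
  class(out) <- c("maldi_spectrum", class(out))
  out
}

#' @export
print.maldi_spectrum <- function(x, ...) {
  cat(sprintf("<maldi_spectrum> %s [%s], %d points, m/z %.1f-%.1f, TIC %.4g\n",
              sample_id(x), spectrum_stage(x), nrow(x),
              min(x$mz), max(x$mz), tic(x)))
  NextMethod()
}

#' Total ion current of a spectrum
#' @param s A `maldi_spectrum`.
#' @return Sum of all intensities.
#' @export
tic <- function(s) sum(s$intensity)

#' @rdname spectrum_tbl
#' @param s A `maldi_spectrum`.
#' @export
sample_id <- function(s) attr(s, "sample_id") %||% "sample"

#' @rdname spectrum_tbl
#' @export
spectrum_stage <- function(s) attr(s, "stage") %||% "raw"

`%||%` <- function(a, b) if (is.null(a)) b else a

# rebuild a spectrum with new intensities, keeping identity, updating stage
set_intensity <- function(s, intensity, stage = spectrum_stage(s)) {
  spectrum_tbl(s$mz, intensity, sample_id = sample_id(s), stage = stage)
}

assert_finite_spectrum <- function(s) {
  if (any(!is.finite(s$intensity))) {
    abort("spectrum contains non-finite intensities.")
  }
  invisible(s)
}
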