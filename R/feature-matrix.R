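#' Build the sample x peak feature matrix of relative peak areas
#'
#' Rows are samples, columns aligned consensus-m/z bins, values relative
#' peak areas. Cells with no detected member are imputed: `fill = "zero"`
#' writes 0; `fill = "interpolate"` writes the mean of the same sample's
#' observed areas in the nearest flanking bins (0 when a flank is missing,
#' e.g. at the edges). The imputation pattern is kept in the `fill_mask`
#' attribute.
#'
#' @param bins A `peak_bins` object from [align_peaks()].
#' @param sample_ids Row roster (defaults to the samples seen in `bins`).
#' @param labels Optional tibble (`sample_id`, `label`) merged in as a
#'   `label` column.
#' @param fill Imputation policy, `"zero"` or `"interpolate"`.
#' @param min_support Drop bins supported by fewer than this fraction of
#'   samples before building the matrix (0 keeps everything).
#' @return A tibble of class `feature_matrix`: `sample_id`, optional
#'   `label`, then one `mz_*` column per bin; attributes `bin_mz`
#'   (numeric consensus m/z per column) and `fill_mask`.
#' @export
build_feature_matrix <- function(bins, sample_ids = NULL, labels = NULL,
                                 fill = c("zero", "interpolate"),
                                 min_support = 0) {
  fill <- match.arg(fill)
  stopifnot(inherits(bins, "peak_bins"))
  members <- bins$members
  keep <- bins$bins$bin_id[bins$bins$support >= min_support]
  members <- members[members$bin_id %in% keep, , drop = FALSE]
  bin_tbl <- bins$bins[bins$bins$bin_id %in% keep, , drop = FALSE]
  if (is.null(sample_ids)) sample_ids <- unique(bins$members$sample_id)
  if (anyDuplicated(members[, c("bin_id", "sample_id")])) {
    abort("a bin holds more than one peak from the same sample.")
  }
  n_s <- length(sample_ids); n_b <- nrow(bin_tbl)
  vals <- matrix(NA_real_, n_s, n_b,
                 dimnames = list(sample_ids, NULL))
  col_of <- setNames(seq_len(n_b), bin_tbl$bin_id)
  vals[cbind(match(members$sample_id, sample_ids),
             col_of[as.character(members$bin_id)])] <- members$area
  mask <- is.na(vals)
  if (fill == "zero") {
    vals[mask] <- 0
  } else {
    for (i in seq_len(n_s)) {
      miss <- which(mask[i, ])
      obs <- which(!mask[i, ])
      for (j in miss) {
        left <- obs[obs < j]; right <- obs[obs > j]
        lv <- if (length(left) > 0) vals[i, max(left)] else NA_real_
        rv <- if (length(right) > 0) vals[i, min(right)] else NA_real_
        vals[i, j] <- if (is.na(lv) || is.na(rv)) 0 else (lv + rv) / 2
      }
    }
  }
  mz_cols <- sprintf("mz_%.2f", bin_tbl$consensus_mz)
  # guard against duplicate rounded names
  mz_cols <- make.unique(mz_cols, sep = "_")
  colnames(vals) <- mz_cols
  out <- bind_cols(tibble(sample_id = sample_ids), as_tibble(vals))
  if (!is.null(labels)) {
    out <- left_join(out, labels, by = "sample_id") |>
      select("sample_id", "label", everything())
  }
  attr(out, "bin_mz") <- setNames(bin_tbl$consensus_mz, mz_cols)
  attr(out, "fill_mask") <- mask
  class(out) <- c("feature_matrix", class(out))
  out
}

#' @importFrom dplyr everything
NULL

#' Feature columns / values of a feature matrix
#' @param fm A `feature_matrix`.
#' @return `feature_mz()`: named numeric vector of consensus m/z per
#'   feature column; `feature_values()`: the numeric matrix (samples x bins).
#' @export
feature_mz <- function(fm) {
  bm <- attr(fm, "bin_mz")
  if (!is.null(bm)) return(bm)
  cols <- grep("^mz_", names(fm), value = TRUE)
  setNames(as.numeric(sub("^mz_", "", cols)), cols)
}

#' @rdname feature_mz
#' @export
feature_values <- function(fm) {
  cols <- names(feature_mz(fm))
  m <- as.matrix(fm[, cols, drop = FALSE])
  rownames(m) <- fm$sample_id
  m
}

#' Differential peptide screen
#'
#' Per aligned bin: `log2fc = log2((mean_TC + eps)/(mean_HC + eps))` with a
#' machine-stable pseudocount, a two-group test on log-transformed areas
#' (Welch's t by default, Mann-Whitney optional), and Benjamini-Hochberg
#' adjusted q-values.
#'
#' @param fm A `feature_matrix` with a `label` column (`TC` / `HC`).
#' @param test `"welch"` or `"wilcoxon"`.
#' @return Tibble of class `differential_table`: `feature`, `mz`,
#'   `mean_tc`, `mean_hc`, `log2fc`, `p_value`, `q_value`.
#' @export
differential_screen <- function(fm, test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  if (!"label" %in% names(fm)) abort("feature matrix carries no labels.")
  vals <- feature_values(fm)
  is_tc <- fm$label == "TC"
  if (sum(is_tc) < 2 || sum(!is_tc) < 2) {
    abort("each class needs at least 2 samples.")
  }
  eps <- max(1e-9 * max(vals), .Machine$double.eps)
  lx <- log(vals + eps)
  mz <- feature_mz(fm)
  p <- vapply(seq_len(ncol(vals)), function(j) {
    a <- lx[is_tc, j]; b <- lx[!is_tc, j]
    if (sd(a) == 0 && sd(b) == 0) {
      return(if (mean(a) == mean(b)) 1 else 0)
    }
    if (test == "welch") t.test(a, b)$p.value
    else suppressWarnings(wilcox.test(a, b)$p.value)
  }, numeric(1))
  out <- tibble(
    feature = colnames(vals),
    mz = unname(mz[colnames(vals)]),
    mean_tc = colMeans(vals[is_tc, , drop = FALSE]),
    mean_hc = colMeans(vals[!is_tc, , drop = FALSE]),
    p_value = p) |>
    mutate(log2fc = log2((.data$mean_tc + eps) / (.data$mean_hc + eps)),
           q_value = p.adjust(.data$p_value, method = "BH")) |>
    select("feature", "mz", "mean_tc", "mean_hc", "log2fc",
           "p_value", "q_value")
  class(out) <- c("differential_table", class(out))
  out
}

#' Top-k selectors for a differential table
#' @param dt A [differential_screen()] result.
#' @param k Number of rows to return.
#' @return The k rows with the largest |log2fc| (`top_k_by_abs_log2fc`) or
#'   the smallest p-values (`top_k_by_p`), in that order.
#' @export
top_k_by_abs_log2fc <- function(dt, k = 20) {
  dt |> arrange(desc(abs(.data$log2fc))) |> slice_head(n = k)
}

#' @rdname top_k_by_abs_log2fc
#' @export
top_k_by_p <- function(dt, k = 20) {
  dt |> arrange(.data$p_value) |> slice_head(n = k)
}
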