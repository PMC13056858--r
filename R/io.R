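#' Read / write spectra as two-column CSV
#'
#' The on-disk form is a plain CSV with header `mz,intensity`, one file per
#' sample; the sample id is the file stem.
#'
#' @param s A [spectrum_tbl()].
#' @param path File path.
#' @export
write_spectrum_csv <- function(s, path) {
  utils::write.csv(as.data.frame(s[, c("mz", "intensity")]), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @param sample_id Sample id (default: file stem).
#' @export
read_spectrum_csv <- function(path, sample_id = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (file.size(path) == 0) abort(paste0("empty spectrum file: ", path))
  df <- utils::read.csv(path)
  if (!all(c("mz", "intensity") %in% names(df)) || nrow(df) == 0) {
    abort(paste0("not a two-column spectrum CSV: ", path))
  }
  if (is.unsorted(df$mz, strictly = TRUE)) {
    warn(paste0("unsorted m/z repaired by sorting: ", path))
    df <- df[order(df$mz), , drop = FALSE]
    df <- df[!duplicated(df$mz), , drop = FALSE]
  }
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]+$", "", basename(path))
  spectrum_tbl(df$mz, df$intensity, sample_id = sample_id)
}

#' Load a directory (CSV) or file (mzML) of spectra
#'
#' @param path Directory of per-sample CSVs, or an mzML file.
#' @param format `"csv"` or `"mzml"`.
#' @return Named list of spectra.
#' @export
load_spectra <- function(path, format = c("csv", "mzml")) {
  format <- match.arg(format)
  if (format == "csv") {
    files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
    if (length(files) == 0) abort(paste0("no CSV spectra under ", path))
    sp <- lapply(files, read_spectrum_csv)
    names(sp) <- vapply(sp, sample_id, character(1))
    return(sp)
  }
  if (!requireNamespace("mzR", quietly = TRUE)) {
    abort("reading mzML requires the mzR package.")
  }
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  hdr <- mzR::header(fh)
  pk <- mzR::peaks(fh)
  if (is.matrix(pk)) pk <- list(pk)
  ids <- if (nrow(hdr) > 0 && "spectrumId" %in% names(hdr)) {
    hdr$spectrumId
  } else sprintf("scan_%03d", seq_along(pk))
  sp <- lapply(seq_along(pk), function(i) {
    m <- pk[[i]]
    o <- order(m[, 1])
    m <- m[o, , drop = FALSE]
    spectrum_tbl(m[, 1], m[, 2], sample_id = ids[i])
  })
  names(sp) <- ids
  sp
}

#' Write spectra to a single mzML file
#'
#' One MS1 scan per sample, scan order preserving the input order. Requires
#' the mzR backend.
#'
#' @param spectra Named list of spectra.
#' @param path Output mzML path.
#' @export
write_spectra_mzml <- function(spectra, path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    abort("writing mzML requires the mzR package.")
  }
  n <- length(spectra)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L,
    peaksCount = vapply(spectra, nrow, integer(1)),
    totIonCurrent = vapply(spectra, tic, numeric(1)),
    retentionTime = as.numeric(seq_len(n)),
    basePeakMZ = vapply(spectra, function(s) s$mz[which.max(s$intensity)],
                        numeric(1)),
    basePeakIntensity = vapply(spectra, function(s) max(s$intensity),
                               numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(spectra, function(s) min(s$mz), numeric(1)),
    highMZ = vapply(spectra, function(s) max(s$mz), numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = names(spectra), centroided = FALSE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_, scanWindowLowerLimit = NA_real_,
    scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE)
  mzR::writeMSData(lapply(spectra, function(s) {
    cbind(mz = s$mz, intensity = s$intensity)
  }), file = path, header = hdr, outformat = "mzml")
  invisible(path)
}

#' Read / write the sample sheet
#' @param samples Tibble (`sample_id`, `label`).
#' @param path CSV path.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.csv(as.data.frame(samples), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "label") %in% names(df))) {
    abort("sample sheet needs sample_id and label columns.")
  }
  as_tibble(df)
}

#' Write / read the feature matrix as CSV
#'
#' Rows are samples (first column `sample_id`), remaining headers are the
#' consensus m/z values rounded to two decimals; labels travel in a
#' separate CSV.
#'
#' @param fm A `feature_matrix`.
#' @param path Values CSV path.
#' @param labels_path Optional labels CSV path.
#' @export
write_feature_matrix <- function(fm, path, labels_path = NULL) {
  vals <- feature_values(fm)
  mz <- feature_mz(fm)
  df <- data.frame(sample_id = fm$sample_id, vals, check.names = FALSE)
  colnames(df) <- c("sample_id", sprintf("%.2f", unname(mz)))
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(labels_path) && "label" %in% names(fm)) {
    write_sample_sheet(fm[, c("sample_id", "label")], labels_path)
  }
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path, labels_path = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  mz <- as.numeric(names(df)[-1])
  cols <- sprintf("mz_%.2f", mz)
  cols <- make.unique(cols, sep = "_")
  vals <- as.matrix(df[, -1, drop = FALSE])
  colnames(vals) <- cols
  out <- bind_cols(tibble(sample_id = as.character(df$sample_id)),
                   as_tibble(vals))
  if (!is.null(labels_path)) {
    out <- left_join(out, read_sample_sheet(labels_path), by = "sample_id") |>
      select("sample_id", "label", everything())
  }
  attr(out, "bin_mz") <- setNames(mz, cols)
  attr(out, "fill_mask") <- matrix(FALSE, nrow(out), length(mz))
  class(out) <- c("feature_matrix", class(out))
  out
}

#' Persist the simulated cohort ground truth as JSON
#' @param truth `cohort$truth`.
#' @param path JSON path.
#' @export
write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(discriminative_mz = truth$discriminative_mz,
         discriminative_log2fc = truth$discriminative_log2fc,
         artifact_mz = truth$artifact_mz,
         per_sample_drift_ppm = as.list(truth$per_sample_drift_ppm)),
    path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}
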