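# standard amino-acid residue masses (Da), monoisotopic and average (IUPAC)
.residue_mono <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
.residue_avg <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
.water_mono <- 18.010565
.water_avg <- 18.01528
.proton <- 1.007276

#' Parse an annotated peptide sequence string
#'
#' Recognizes three dialects: a bare sequence (`"GASP"`), dot-flanked
#' (`"R.MLLK.A"`, single preceding/following residues), and bracket-flanked
#' (`"[P].TSAH.[P]"`). Returns the stripped core sequence, the flanking
#' residues (NA when absent) and the residue count.
#'
#' @param raw Annotation string (non-empty).
#' @return Tibble row: `raw`, `core_sequence`, `n_term_flank`,
#'   `c_term_flank`, `length`.
#' @export
parse_annotation <- function(raw) {
  if (length(raw) != 1 || !nzchar(raw)) abort("annotation must be a non-empty string.")
  n_fl <- NA_character_; c_fl <- NA_character_
  core <- raw
  m <- regmatches(raw, regexec("^\\[([A-Za-z-])\\]\\.([A-Za-z]+)\\.\\[([A-Za-z-])\\]$", raw))[[1]]
  if (length(m) == 4) {
    n_fl <- m[2]; core <- m[3]; c_fl <- m[4]
  } else {
    m <- regmatches(raw, regexec("^([A-Za-z-])\\.([A-Za-z]+)\\.([A-Za-z-])$", raw))[[1]]
    if (length(m) == 4) {
      n_fl <- m[2]; core <- m[3]; c_fl <- m[4]
    }
  }
  residues <- strsplit(core, "")[[1]]
  bad <- setdiff(unique(residues), names(.residue_mono))
  if (length(bad) > 0) {
    abort(sprintf("illegal residue character '%s' in \"%s\".", bad[1], raw))
  }
  tibble(raw = raw, core_sequence = core, n_term_flank = n_fl,
         c_term_flank = c_fl, length = length(residues))
}

#' Format a parsed annotation back to its string form
#' @param core_sequence Core residue string.
#' @param n_term_flank,c_term_flank Optional single flank residues.
#' @param dialect `"bare"`, `"dot"` or `"bracket"`.
#' @return The annotation string.
#' @export
format_annotation <- function(core_sequence, n_term_flank = NA,
                              c_term_flank = NA,
                              dialect = c("bare", "dot", "bracket")) {
  dialect <- match.arg(dialect)
  if (dialect == "bare" || is.na(n_term_flank)) return(core_sequence)
  if (dialect == "dot") {
    paste0(n_term_flank, ".", core_sequence, ".", c_term_flank)
  } else {
    paste0("[", n_term_flank, "].", core_sequence, ".[", c_term_flank, "]")
  }
}

#' Theoretical peptide mass
#'
#' Sum of standard residue masses plus water, optionally plus one proton
#' (the singly charged MALDI ion, `[M+H]+`).
#'
#' @param core_sequence Residue string (standard 20 letters).
#' @param mode `"monoisotopic"` or `"average"`.
#' @param protonated Add one proton mass.
#' @return Mass in Da.
#' @export
peptide_mass <- function(core_sequence, mode = c("monoisotopic", "average"),
                         protonated = FALSE) {
  mode <- match.arg(mode)
  if (!nzchar(core_sequence)) abort("empty sequence.")
  residues <- strsplit(core_sequence, "")[[1]]
  tab <- if (mode == "monoisotopic") .residue_mono else .residue_avg
  bad <- setdiff(unique(residues), names(tab))
  if (length(bad) > 0) {
    abort(sprintf("illegal residue character '%s'.", bad[1]))
  }
  m <- sum(tab[residues]) +
    if (mode == "monoisotopic") .water_mono else .water_avg
  if (protonated) m <- m + .proton
  unname(m)
}

#' Match an observed peak m/z against candidate peptides
#'
#' For each candidate the four theoretical masses (monoisotopic / average,
#' neutral / protonated) are tried and the best (smallest |delta ppm|) is
#' reported; candidates within `tol_ppm` are returned sorted by |delta
#' ppm|. Observed MALDI masses in annotation tables mix conventions, so
#' matching is deliberately tolerance-based and mode-agnostic.
#'
#' @param observed_mz Observed peak m/z (Da).
#' @param candidates Tibble with a `core_sequence` column (e.g. rows from
#'   [parse_annotation()], possibly carrying `gene`/`accession` columns), or
#'   a character vector of sequences.
#' @param tol_ppm Match tolerance in ppm (> 0).
#' @return Tibble of matching candidates with `theoretical_mass`, `mode`,
#'   `protonated`, `delta_ppm`, sorted by |delta_ppm|; zero rows when
#'   nothing matches.
#' @export
match_observed <- function(observed_mz, candidates, tol_ppm = 500) {
  if (tol_ppm <= 0) abort("tol_ppm must be > 0.")
  if (is.character(candidates)) candidates <- tibble(core_sequence = candidates)
  best <- lapply(seq_len(nrow(candidates)), function(i) {
    seqc <- candidates$core_sequence[i]
    grid <- expand.grid(mode = c("monoisotopic", "average"),
                        protonated = c(FALSE, TRUE),
                        stringsAsFactors = FALSE)
    masses <- mapply(function(mo, pr) peptide_mass(seqc, mo, pr),
                     grid$mode, grid$protonated)
    dppm <- (masses - observed_mz) / observed_mz * 1e6
    j <- which.min(abs(dppm))
    bind_cols(candidates[i, , drop = FALSE],
              tibble(theoretical_mass = masses[j], mode = grid$mode[j],
                     protonated = grid$protonated[j], delta_ppm = dppm[j]))
  })
  out <- bind_rows(best)
  out <- out[abs(out$delta_ppm) <= tol_ppm, , drop = FALSE]
  out[order(abs(out$delta_ppm)), , drop = FALSE]
}

#' Example annotated serum peptide panel
#'
#' An annotated thyroid-cancer serum peptidome panel (observed MALDI
#' masses, annotated sequences in mixed flank dialects, printed residue
#' counts, UniProt accessions and gene symbols) shipped as plain CSV, used
#' throughout the documentation and tests.
#'
#' @return Tibble with columns `observed_mass`, `annotated_sequence`,
#'   `length`, `accession`, `gene`, `protein`.
#' @export
example_peptide_panel <- function() {
  path <- system.file("extdata", "serum_peptide_panel.csv",
                      package = "maldiml", mustWork = TRUE)
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
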