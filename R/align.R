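#' Greedy cross-sample peak alignment at ppm tolerance
#'
#' Pools every sample's detected peaks and groups them into consensus bins
#' with an iterative greedy procedure: the unassigned peak with the largest
#' support-weighted intensity (total unassigned area within the tolerance
#' window around it) seeds a bin; every sample's nearest unassigned peak
#' within `tol_ppm` of the seed joins (at most one per sample); the
#' consensus m/z is the area-weighted mean of the members. Once all peaks
#' are seeded, membership is refined by reassigning each peak to its
#' nearest bin consensus (per-sample conflicts resolved by distance, losers
#' falling back to their previous bin or a fresh singleton) until stable or
#' `max_iter` passes. Every member ends within `tol_ppm` of its final
#' consensus (hard assertion).
#'
#' @param peaks Either one pooled peak tibble with a `sample_id` column or a
#'   list of per-sample peak tibbles.
#' @param tol_ppm Alignment tolerance in ppm, measured against the bin
#'   consensus m/z.
#' @param max_iter Maximum refinement passes.
#' @param sample_ids Full roster of samples (defaults to those seen in
#'   `peaks`); the denominator of bin support.
#' @return A list of class `peak_bins`: `bins` (tibble `bin_id`,
#'   `consensus_mz`, `n_members`, `support`) ordered by consensus m/z, and
#'   `members` (tibble `bin_id`, `sample_id`, `mz`, `area`).
#' @export
align_peaks <- function(peaks, tol_ppm = 2500, max_iter = 10,
                        sample_ids = NULL) {
  if (is.list(peaks) && !is.data.frame(peaks)) peaks <- bind_rows(peaks)
  if (is.null(sample_ids)) sample_ids <- unique(peaks$sample_id)
  n_samples <- length(sample_ids)
  if (nrow(peaks) == 0) {
    return(structure(list(
      bins = tibble(bin_id = integer(), consensus_mz = numeric(),
                    n_members = integer(), support = numeric()),
      members = tibble(bin_id = integer(), sample_id = character(),
                       mz = numeric(), area = numeric()),
      tol_ppm = tol_ppm, n_samples = n_samples), class = "peak_bins"))
  }
  ord <- order(peaks$mz)
  mz <- peaks$mz[ord]; area <- peaks$area[ord]
  sample <- as.character(peaks$sample_id[ord])
  n <- length(mz)
  tol <- tol_ppm * 1e-6
  bin_of <- rep(NA_integer_, n)
  n_bins <- 0L

  # --- greedy seeding ---------------------------------------------------
  lo <- findInterval(mz * (1 - tol), mz, left.open = TRUE) + 1L
  hi <- findInterval(mz * (1 + tol), mz)
  while (anyNA(bin_of)) {
    un <- is.na(bin_of)
    cs <- c(0, cumsum(ifelse(un, area, 0)))
    score <- cs[hi + 1L] - cs[lo]
    score[!un] <- -Inf
    seed <- which.max(score)  # ties: first (lowest m/z)
    idx <- lo[seed]:hi[seed]
    idx <- idx[is.na(bin_of[idx])]
    # one member per sample: nearest to the seed m/z
    keep <- idx[order(abs(mz[idx] - mz[seed]))]
    keep <- keep[!duplicated(sample[keep])]
    n_bins <- n_bins + 1L
    bin_of[keep] <- n_bins
  }

  consensus_of <- function(bin_of, nb) {
    num <- rep(NA_real_, nb)
    agg_w <- rowsum(area, bin_of)
    agg_m <- rowsum(mz * area, bin_of)
    ids <- as.integer(rownames(agg_w))
    num[ids] <- agg_m[, 1] / agg_w[, 1]
    num
  }

  # --- iterative refinement against consensus m/z -----------------------
  cons <- consensus_of(bin_of, n_bins)
  for (it in seq_len(max_iter)) {
    live <- which(!is.na(cons))
    co <- order(cons[live])
    cvals <- cons[live][co]; cids <- live[co]
    pos <- findInterval(mz, cvals)
    lo_i <- pmax(pos, 1L); hi_i <- pmin(pos + 1L, length(cvals))
    d_lo <- abs(mz - cvals[lo_i]); d_hi <- abs(mz - cvals[hi_i])
    near <- ifelse(d_lo <= d_hi, lo_i, hi_i)
    dist <- pmin(d_lo, d_hi)
    desired <- cids[near]
    within <- dist / cvals[near] <= tol
    new_bin <- rep(NA_integer_, n)
    # pass 1: nearest-consensus claims, per (bin, sample) nearest wins
    p1 <- which(within)
    p1 <- p1[order(dist[p1])]
    key1 <- paste(desired[p1], sample[p1])
    win <- !duplicated(key1)
    new_bin[p1[win]] <- desired[p1[win]]
    claimed <- key1[win]
    # pass 2: losers fall back to their previous bin when still in tolerance
    p2 <- which(is.na(new_bin))
    prev <- bin_of[p2]
    ok_prev <- !is.na(cons[prev]) & abs(mz[p2] - cons[prev]) / cons[prev] <= tol
    p2 <- p2[ok_prev]; prev <- prev[ok_prev]
    o2 <- order(abs(mz[p2] - cons[prev]))
    p2 <- p2[o2]; prev <- prev[o2]
    key2 <- paste(prev, sample[p2])
    free <- !(key2 %in% claimed) & !duplicated(key2)
    new_bin[p2[free]] <- prev[free]
    # pass 3: anything left opens a singleton bin
    p3 <- which(is.na(new_bin))
    if (length(p3) > 0) {
      new_ids <- n_bins + seq_along(p3)
      new_bin[p3] <- new_ids
      n_bins <- n_bins + length(p3)
      cons <- c(cons, rep(NA_real_, length(p3)))
    }
    stable <- identical(new_bin, bin_of)
    bin_of <- new_bin
    cons <- consensus_of(bin_of, n_bins)
    if (stable) break
  }

  # eviction cleanup: consensus drift can leave a member just outside
  # tolerance; such peaks are split off into singleton bins
  for (pass in 1:5) {
    viol <- which(abs(mz - cons[bin_of]) / cons[bin_of] > tol)
    if (length(viol) == 0) break
    new_ids <- n_bins + seq_along(viol)
    bin_of[viol] <- new_ids
    n_bins <- n_bins + length(viol)
    cons <- consensus_of(bin_of, n_bins)
  }

  # merge pass: two neighbouring bins with disjoint samples collapse into
  # one when the combined area-weighted consensus keeps every member within
  # tolerance (members may span up to 2x tol around a well-placed
  # consensus, which seed-centred windows cannot discover)
  repeat {
    members_of <- split(seq_along(bin_of), bin_of)
    live <- as.integer(names(members_of))
    ord <- order(cons[live])
    merged <- FALSE
    for (i in seq_len(length(ord) - 1)) {
      b1 <- live[ord[i]]; b2 <- live[ord[i + 1]]
      m1 <- members_of[[as.character(b1)]]
      m2 <- members_of[[as.character(b2)]]
      if (any(sample[m1] %in% sample[m2])) next
      idx <- c(m1, m2)
      wc <- sum(mz[idx] * area[idx]) / sum(area[idx])
      if (all(abs(mz[idx] - wc) / wc <= tol)) {
        bin_of[m2] <- b1
        cons[b1] <- wc; cons[b2] <- NA_real_
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }

  # compact bin ids, order by consensus m/z
  occupied <- sort(unique(bin_of))
  o <- order(cons[occupied])
  relabel <- integer(n_bins)
  relabel[occupied[o]] <- seq_along(occupied)
  bin_of <- relabel[bin_of]

  members <- tibble(bin_id = bin_of, sample_id = sample, mz = mz,
                    area = area) |> arrange(.data$bin_id, .data$sample_id)
  bins <- members |>
    group_by(.data$bin_id) |>
    summarise(consensus_mz = sum(.data$mz * .data$area) / sum(.data$area),
              n_members = n(), .groups = "drop") |>
    mutate(support = .data$n_members / n_samples)
  stopifnot(all(abs(members$mz - bins$consensus_mz[members$bin_id]) /
                  bins$consensus_mz[members$bin_id] <= tol + 1e-12))
  structure(list(bins = bins, members = members, tol_ppm = tol_ppm,
                 n_samples = n_samples), class = "peak_bins")
}

#' @export
print.peak_bins <- function(x, ...) {
  cat(sprintf("<peak_bins> %d bins from %d peaks across %d samples (tol %g ppm)\n",
              nrow(x$bins), nrow(x$members), x$n_samples, x$tol_ppm))
  invisible(x)
}
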