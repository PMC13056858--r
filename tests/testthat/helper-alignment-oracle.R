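# Exhaustive alignment oracle: enumerates assignments of peaks to bins by
# branch and bound and returns the tolerance-feasible partition minimizing
# bin count, ties broken by total centroid dispersion (sum |mz - consensus|).
# A bin is feasible when every member lies within tol_ppm of its
# area-weighted consensus and holds at most one peak per sample. Because
# feasibility is not monotone in the member set (a new member can shift the
# consensus towards an outlier), full tolerance is only checked on complete
# partitions; during the search only two sound prunes apply: per-sample
# uniqueness, and an m/z span wider than 2x tolerance (no consensus can
# cover both extremes).
oracle_align <- function(peaks, tol_ppm = 2500) {
  o <- order(peaks$mz)
  peaks <- peaks[o, , drop = FALSE]
  n <- nrow(peaks)
  tol <- tol_ppm * 1e-6
  best <- list(n_bins = Inf, disp = Inf, assign = NULL)

  bin_feasible <- function(idx) {
    cons <- sum(peaks$mz[idx] * peaks$area[idx]) / sum(peaks$area[idx])
    all(abs(peaks$mz[idx] - cons) / cons <= tol)
  }
  partition_ok <- function(assign) {
    all(vapply(unique(assign), function(b) {
      bin_feasible(which(assign == b))
    }, logical(1)))
  }
  dispersion <- function(assign) {
    sum(vapply(unique(assign), function(b) {
      idx <- which(assign == b)
      cons <- sum(peaks$mz[idx] * peaks$area[idx]) / sum(peaks$area[idx])
      sum(abs(peaks$mz[idx] - cons))
    }, numeric(1)))
  }
  recurse <- function(i, assign, n_bins) {
    if (n_bins > best$n_bins) return()
    if (i > n) {
      if (!partition_ok(assign)) return()
      d <- dispersion(assign)
      if (n_bins < best$n_bins ||
          (n_bins == best$n_bins && d < best$disp)) {
        best <<- list(n_bins = n_bins, disp = d, assign = assign)
      }
      return()
    }
    for (b in seq_len(n_bins)) {
      members <- which(assign == b)
      if (peaks$sample_id[i] %in% peaks$sample_id[members]) next
      span_mz <- range(peaks$mz[c(members, i)])
      if (diff(span_mz) / span_mz[1] > 2 * tol) next
      cand <- assign
      cand[i] <- b
      recurse(i + 1, cand, n_bins)
    }
    cand <- assign
    cand[i] <- n_bins + 1
    recurse(i + 1, cand, n_bins + 1)
  }
  recurse(1, integer(n), 0)
  # report assignments in the caller's original row order
  assign_orig <- integer(n)
  assign_orig[o] <- best$assign
  list(n_bins = best$n_bins, disp = best$disp, assign = assign_orig)
}

# random clustered alignment instance: a few species at well-separated m/z,
# per-sample centroids jittered within the tolerance, one peak per sample
# per species
random_align_instance <- function(seed, tol_ppm = 2500) {
  withr::with_seed(seed, {
    n_species <- sample(2:4, 1)
    n_samples <- 3
    centres <- sort(runif(n_species, 1000, 9000))
    # enforce separation of at least 4x tolerance
    for (j in seq_len(n_species)[-1]) {
      centres[j] <- max(centres[j],
                        centres[j - 1] * (1 + 4 * tol_ppm * 1e-6) + 1)
    }
    rows <- list()
    for (j in seq_len(n_species)) {
      present <- which(runif(n_samples) < 0.9)
      if (length(present) == 0) present <- 1
      for (s in present) {
        jitter <- runif(1, -0.7, 0.7) * tol_ppm * 1e-6 * centres[j]
        rows[[length(rows) + 1]] <- tibble::tibble(
          sample_id = sprintf("s%d", s),
          mz = centres[j] + jitter,
          area = runif(1, 10, 100), snr = 10)
      }
    }
    dplyr::bind_rows(rows)
  })
}

# partition signature invariant to bin labelling: sorted member lists
partition_signature <- function(assign, mz) {
  sig <- split(sort(mz), assign[order(mz)])
  unname(lapply(sig[order(vapply(sig, min, numeric(1)))], identity))
}
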