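# Bisecting k-means: start from one cluster, repeatedly 2-means-split the
# cluster with the largest within-cluster sum of squares until k clusters.
bisecting_kmeans <- function(x, k = 2, seed = 1L, nstart = 5) {
  n <- nrow(x)
  assign <- rep(1L, n)
  wss <- function(idx) {
    if (length(idx) < 2) return(0)
    sum(scale(x[idx, , drop = FALSE], scale = FALSE)^2)
  }
  with_local_seed(seed, {
    while (length(unique(assign)) < k) {
      sizes <- table(assign)
      cand <- as.integer(names(sizes)[sizes >= 2])
      if (length(cand) == 0) break
      target <- cand[which.max(vapply(cand, function(cl) {
        wss(which(assign == cl))
      }, numeric(1)))]
      idx <- which(assign == target)
      km <- kmeans(x[idx, , drop = FALSE], centers = 2, nstart = nstart)
      new_id <- max(assign) + 1L
      assign[idx[km$cluster == 2]] <- new_id
    }
  })
  as.integer(factor(assign))
}

# BIRCH-style clustering: a flat clustering-feature (CF) pass absorbs each
# point into the nearest subcluster within a distance threshold (new
# subclusters open when none qualifies), then the subcluster centroids are
# merged down to k groups by Ward hierarchical clustering.
birch_cluster <- function(x, k = 2, threshold = NULL, branching = 50) {
  n <- nrow(x)
  if (is.null(threshold)) {
    samp <- x[seq(1, n, length.out = min(n, 200)), , drop = FALSE]
    threshold <- 0.5 * median(dist(samp))
    if (!is.finite(threshold) || threshold <= 0) threshold <- 1
  }
  cent <- matrix(x[1, ], 1); cnt <- 1L
  assign_cf <- integer(n); assign_cf[1] <- 1L
  for (i in seq_len(n)[-1]) {
    d <- sqrt(colSums((t(cent) - x[i, ])^2))
    j <- which.min(d)
    if (d[j] <= threshold && nrow(cent) >= 1) {
      # absorb: update running centroid
      cent[j, ] <- (cent[j, ] * cnt[j] + x[i, ]) / (cnt[j] + 1)
      cnt[j] <- cnt[j] + 1L
      assign_cf[i] <- j
    } else {
      cent <- rbind(cent, x[i, ])
      cnt <- c(cnt, 1L)
      assign_cf[i] <- nrow(cent)
    }
  }
  if (nrow(cent) <= k) {
    merged <- seq_len(nrow(cent))
  } else {
    hc <- stats::hclust(dist(cent), method = "ward.D2")
    merged <- stats::cutree(hc, k = k)
  }
  as.integer(factor(merged[assign_cf]))
}

#' 2-D embedding of the samples
#'
#' Low-dimensional map for visual comparison of clustering structure,
#' via the package's exact t-SNE (default) or PCA.
#'
#' @param fm A `feature_matrix`.
#' @param method `"tsne"` or `"pca"`.
#' @param seed Seed for t-SNE.
#' @return Tibble `sample_id`, optional `label`, `dim1`, `dim2`.
#' @export
embed_samples <- function(fm, method = c("tsne", "pca"), seed = 1L) {
  method <- match.arg(method)
  reduce_dimensions(fm, method = method, dims = 2, seed = seed)
}

#' Unsupervised clustering check with embedding
#'
#' Runs bisecting k-means and BIRCH on the (optionally feature-restricted)
#' matrix, scores each clustering against the diagnosis labels with the
#' adjusted Rand index, and attaches a 2-D embedding.
#'
#' @param fm A `feature_matrix` with labels.
#' @param features Optional subset of feature columns (e.g. the core set).
#' @param k Number of clusters (>= 2).
#' @param seed Seed (k-means restarts, embedding).
#' @param embed_method Passed to [embed_samples()].
#' @return Tibble of class `cluster_result`: one row per algorithm with
#'   `algorithm`, `ari`; attributes `assignments` (named list) and
#'   `embedding`.
#' @export
cluster_and_embed <- function(fm, features = NULL, k = 2, seed = 1L,
                              embed_method = "tsne") {
  if (k < 2) abort("k must be >= 2.")
  if (nrow(fm) <= k) abort("need more samples than clusters.")
  sub <- fm
  if (!is.null(features)) {
    if (inherits(features, "core_feature_set")) features <- features$shared
    keep <- c(intersect(c("sample_id", "label"), names(fm)), features)
    sub <- fm[, keep]
    attr(sub, "bin_mz") <- feature_mz(fm)[features]
    class(sub) <- class(fm)
  }
  x <- feature_values(sub)
  xs <- scale(x)
  xs[, attr(xs, "scaled:scale") == 0] <- 0
  assignments <- list(
    bisecting_kmeans = bisecting_kmeans(xs, k = k, seed = seed),
    birch = birch_cluster(xs, k = k))
  ari <- vapply(assignments, function(a) {
    if ("label" %in% names(fm)) {
      mclust::adjustedRandIndex(a, fm$label)
    } else NA_real_
  }, numeric(1))
  out <- tibble(algorithm = names(assignments), ari = unname(ari))
  attr(out, "assignments") <- assignments
  attr(out, "embedding") <- embed_samples(sub, method = embed_method,
                                          seed = seed)
  class(out) <- c("cluster_result", class(out))
  out
}
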