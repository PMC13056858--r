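#' Dimensionality reduction for visualization
#'
#' Projects the feature matrix to 2 or 3 coordinates with PCA
#' (deterministic), kernel PCA (RBF kernel), or t-SNE (exact
#' gradient-descent implementation, seeded).
#'
#' @param fm A `feature_matrix`.
#' @param method `"pca"`, `"kpca"` or `"tsne"`.
#' @param dims 2 or 3.
#' @param seed Seed for the stochastic methods.
#' @param perplexity t-SNE perplexity.
#' @return Tibble: `sample_id`, optional `label`, `dim1`..`dimK`; PCA also
#'   attaches the per-component explained-variance fractions as attribute
#'   `explained_variance`.
#' @export
reduce_dimensions <- function(fm, method = c("pca", "kpca", "tsne"),
                              dims = 2, seed = 1L, perplexity = 30) {
  method <- match.arg(method)
  if (!dims %in% c(2, 3)) abort("dims must be 2 or 3.")
  x <- feature_values(fm)
  if (nrow(x) < dims + 1) abort("need at least dims + 1 samples.")
  coords <- switch(method,
    pca = {
      p <- prcomp(x, center = TRUE, scale. = FALSE)
      out <- p$x[, seq_len(dims), drop = FALSE]
      attr(out, "explained_variance") <- p$sdev^2 / sum(p$sdev^2)
      out
    },
    kpca = {
      kp <- kernlab::kpca(x, kernel = "rbfdot", features = dims)
      kernlab::rotated(kp)
    },
    tsne = tsne_exact(x, dims = dims, perplexity = perplexity, seed = seed))
  out <- bind_cols(
    tibble(sample_id = fm$sample_id),
    if ("label" %in% names(fm)) tibble(label = fm$label),
    as_tibble(setNames(as.data.frame(unname(coords[, seq_len(dims)])),
                       paste0("dim", seq_len(dims)))))
  if (method == "pca") {
    attr(out, "explained_variance") <- attr(coords, "explained_variance")
  }
  out
}

# Exact t-SNE (quadratic in n): Gaussian input affinities calibrated to the
# target perplexity by bisection, Student-t output kernel, gradient descent
# with momentum and early exaggeration. Suitable for cohort-scale n.
tsne_exact <- function(x, dims = 2, perplexity = 30, seed = 1L,
                       max_iter = 400, eta = 200) {
  n <- nrow(x)
  perplexity <- min(perplexity, floor((n - 1) / 3))
  if (perplexity < 2) perplexity <- 2
  # PCA-compress to at most 30 columns first (standard practice)
  if (ncol(x) > 30) {
    x <- prcomp(x, center = TRUE, scale. = FALSE)$x[, seq_len(min(30, n - 1)),
                                                    drop = FALSE]
  }
  d2 <- as.matrix(dist(x))^2
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    lo <- 1e-20; hi <- 1e20; beta <- 1
    for (it in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw <= 0) { beta <- beta / 2; next }
      H <- log(sw) + beta * sum(di * w) / sw
      if (abs(H - target) < 1e-5) break
      if (H > target) { lo <- beta; beta <- if (hi < 1e19) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- (beta + lo) / 2 }
    }
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  with_local_seed(seed, {
    Y <- matrix(rnorm(n * dims, sd = 1e-4), n, dims)
  })
  inc <- matrix(0, n, dims)
  for (iter in seq_len(max_iter)) {
    ex <- if (iter <= 100) 4 else 1
    num <- 1 / (1 + as.matrix(dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (ex * P - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (iter <= 250) 0.5 else 0.8
    inc <- mom * inc - eta * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
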