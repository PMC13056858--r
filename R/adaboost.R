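# Discrete AdaBoost (SAMME) over shallow rpart trees; binary labels.
# Margin F(x) = sum_m alpha_m h_m(x), h in {-1,+1}; probability via the
# logistic map of the margin (Friedman's population minimiser is
# p = 1/(1+exp(-2F)); the factor 2 only rescales, ranking is unchanged).
ada_fit <- function(x, y, n_rounds = 80, maxdepth = 2, seed = 1L) {
  df <- as.data.frame(x)
  yf <- factor(y, levels = c("HC", "TC"))
  n <- nrow(df)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  with_local_seed(seed, {
    for (m in seq_len(n_rounds)) {
      fit <- rpart::rpart(
        yf ~ ., data = cbind(df, yf = yf), weights = w, method = "class",
        control = rpart::rpart.control(maxdepth = maxdepth, cp = 0,
                                       minsplit = 10, xval = 0))
      pred <- predict(fit, df, type = "class")
      miss <- pred != yf
      err <- sum(w[miss])
      if (err <= 0) { stumps[[m]] <- fit; alphas[m] <- 10; break }
      if (err >= 0.5) break
      alpha <- 0.5 * log((1 - err) / err)
      stumps[[m]] <- fit; alphas[m] <- alpha
      w <- w * exp(ifelse(miss, alpha, -alpha))
      w <- w / sum(w)
    }
  })
  if (length(stumps) == 0) {  # degenerate: constant majority model
    stumps <- list(NULL)
    alphas <- 0
    maj <- names(which.max(table(yf)))
    return(structure(list(stumps = stumps, alphas = alphas,
                          majority = maj), class = "ada_boost"))
  }
  structure(list(stumps = stumps, alphas = alphas, majority = NULL),
            class = "ada_boost")
}

ada_margin <- function(fit, newx) {
  df <- as.data.frame(newx)
  if (!is.null(fit$majority)) {
    return(rep(if (fit$majority == "TC") 1 else -1, nrow(df)) * 0)
  }
  f <- rep(0, nrow(df))
  for (m in seq_along(fit$stumps)) {
    pred <- predict(fit$stumps[[m]], df, type = "class")
    f <- f + fit$alphas[m] * ifelse(pred == "TC", 1, -1)
  }
  f
}

#' @export
predict.ada_boost <- function(object, newdata, ...) {
  plogis(2 * ada_margin(object, newdata))
}
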