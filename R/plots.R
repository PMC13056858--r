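#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   geom_abline geom_col labs theme_minimal coord_cartesian facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot a spectrum (optionally with its fitted baseline)
#' @param object A `maldi_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.maldi_spectrum <- function(object, ...) {
  p <- ggplot(object, aes(x = .data$mz, y = .data$intensity)) +
    geom_line(linewidth = 0.3) +
    labs(x = "m/z (Da)", y = "intensity",
         title = sprintf("%s [%s]", sample_id(object),
                         spectrum_stage(object))) +
    theme_minimal()
  bl <- attr(object, "baseline")
  if (!is.null(bl)) {
    p <- p + geom_line(data = tibble(mz = object$mz, intensity = bl),
                       colour = "red", linewidth = 0.3)
  }
  p
}

#' Decision-curve plot: model net benefit vs the reference policies
#' @param object A [dca_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dca_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$threshold)) +
    geom_line(aes(y = .data$nb), colour = "steelblue") +
    geom_line(aes(y = .data$nb_all), colour = "grey40", linetype = 2) +
    geom_hline(yintercept = 0, colour = "grey40") +
    coord_cartesian(ylim = c(-0.05, max(object$nb, object$nb_all, 0) + 0.05)) +
    labs(x = "threshold probability", y = "net benefit",
         title = sprintf("decision curve (area %.3f)", attr(object, "area"))) +
    theme_minimal()
}

#' Volcano plot of the differential screen
#' @param object A [differential_screen()] table.
#' @param q_cut Highlight threshold on the BH q-value.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.differential_table <- function(object, q_cut = 0.05, ...) {
  ggplot(object, aes(x = .data$log2fc, y = -log10(.data$p_value),
                     colour = .data$q_value < q_cut)) +
    geom_point(size = 0.8, alpha = 0.7) +
    labs(x = "log2 fold change (TC vs HC)", y = "-log10 p",
         colour = sprintf("q < %.2f", q_cut)) +
    theme_minimal()
}

#' ROC curves for every benched family
#' @param metrics An [evaluate_classifiers()] result.
#' @return A ggplot of per-family test-set ROC curves.
#' @export
plot_roc_curves <- function(metrics) {
  probs <- attr(metrics, "probabilities")
  if (is.null(probs)) abort("metrics carry no stored probabilities.")
  pts <- probs |>
    group_by(.data$family) |>
    summarise(roc_points(.data$prob, .data$label), .groups = "drop")
  ggplot(pts, aes(x = .data$fpr, y = .data$tpr, colour = .data$family)) +
    geom_line() +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    labs(x = "false positive rate", y = "true positive rate") +
    theme_minimal()
}

#' Bar plot of aggregated feature importance
#' @param tbl Importance tibble (`method`, `family`, `feature`, `score`).
#' @param top_n Features shown.
#' @return A ggplot.
#' @export
plot_importance <- function(tbl, top_n = 20) {
  agg <- aggregate_importance(tbl) |> slice_head(n = top_n)
  agg$feature <- factor(agg$feature, levels = rev(agg$feature))
  ggplot(agg, aes(x = .data$mean_score, y = .data$feature)) +
    geom_col(fill = "steelblue") +
    labs(x = "mean importance", y = NULL,
         title = unique(tbl$method)[1]) +
    theme_minimal()
}

#' Embedding coloured by cluster assignment and by diagnosis
#' @param object A [cluster_and_embed()] result.
#' @param algorithm Which assignment to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cluster_result <- function(object, algorithm = "bisecting_kmeans",
                                    ...) {
  emb <- attr(object, "embedding")
  emb$cluster <- factor(attr(object, "assignments")[[algorithm]])
  p <- ggplot(emb, aes(x = .data$dim1, y = .data$dim2,
                       colour = .data$cluster))
  if ("label" %in% names(emb)) {
    p <- p + geom_point(aes(shape = .data$label), size = 1.5)
  } else {
    p <- p + geom_point(size = 1.5)
  }
  p + labs(title = algorithm) + theme_minimal()
}
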