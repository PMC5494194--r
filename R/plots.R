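#' Plot a saturation curve
#'
#' Mean number of distinct merged regions as samples are added in random
#' order, with the 95% percentile band across orderings.
#'
#' @param object A `saturation_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.saturation_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_samples, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                         fill = "grey80") +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Samples added", y = "Distinct accessible regions",
                  title = "Consensus map saturation") +
    ggplot2::theme_minimal()
}

#' Plot an accessibility corridor
#'
#' Per-base cohort mean with the 5-95 and 25-75 percentile corridors.
#'
#' @param object A `corridor_track`.
#' @param ... Unused.
#' @return A ggplot object (facetted by chromosome).
#' @export
autoplot.corridor_track <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pos)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p5, ymax = .data$p95),
                         fill = "#c6dbef") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p25, ymax = .data$p75),
                         fill = "#6baed6") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), colour = "#08306b") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "Position (bp)", y = "Normalised coverage",
                  title = "Chromatin accessibility corridor") +
    ggplot2::theme_minimal()
}

#' Plot a cross-validated ROC curve
#'
#' The pooled out-of-fold ROC curve with its AUC, optionally overlaid with
#' shuffled-label null curves' AUC distribution.
#'
#' @param object A `loocv_result`.
#' @param null_dist Optional `null_distribution` to annotate.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.loocv_result <- function(object, null_dist = NULL, ...) {
  p <- ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.9, colour = "#08519c") +
    ggplot2::annotate("text", x = 0.7, y = 0.15,
                      label = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = "Patient-aware cross-validated ROC") +
    ggplot2::theme_minimal()
  if (!is.null(null_dist)) {
    p <- p + ggplot2::annotate(
      "text", x = 0.7, y = 0.07,
      label = sprintf("null mean AUC = %.3f", mean(null_dist$auc)),
      colour = "grey40"
    )
  }
  p
}

#' Plot a PCA projection
#'
#' @param object A `pca_projection`.
#' @param colour_by Optional named vector or tibble (`sample_id`, value)
#'   used to colour samples (e.g. IGHV labels).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pca_projection <- function(object, colour_by = NULL, ...) {
  ev <- attr(object, "explained_variance")
  df <- object
  if (!is.null(colour_by)) {
    if (is.data.frame(colour_by)) {
      colour_by <- setNames(colour_by[[2]], colour_by$sample_id)
    }
    df$group <- as.character(colour_by[df$sample_id])
  }
  aes <- if (is.null(colour_by)) {
    ggplot2::aes(x = .data$PC1, y = .data$PC2)
  } else {
    ggplot2::aes(x = .data$PC1, y = .data$PC2, colour = .data$group)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ev[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ev[2]),
      colour = NULL, title = "Principal component analysis"
    ) +
    ggplot2::theme_minimal()
}

#' Plot differential connectivity between two networks
#'
#' Top differentially connected nodes by absolute log2 change of
#' edge-normalised degree.
#'
#' @param dc A `differential_connectivity`.
#' @param top Number of nodes to show.
#' @return A ggplot object.
#' @export
plot_differential_connectivity <- function(dc, top = 20) {
  df <- head(dc$shared, top)
  df$node <- factor(df$node, levels = rev(df$node))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_change, y = .data$node)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$log2_change > 0), show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2171b5", `FALSE` = "#cb181d")) +
    ggplot2::labs(x = "log2 normalised-degree change (A vs B)", y = NULL,
                  title = "Differential network connectivity") +
    ggplot2::theme_minimal()
}
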