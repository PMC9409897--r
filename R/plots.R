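# ggplot2 views of the result types. These mirror the usual metabolomics
# figures: volcano plots, PCA score plots, per-class DAM bars.

#' Volcano plot of DAM records
#'
#' @param dams Flagged DAM tibble ([call_significant()] output) or the
#'   output of [volcano_data()].
#' @param lfc_threshold,alpha Guide lines (match the thresholds used for the
#'   calls).
#' @return A ggplot object, faceted by comparison.
#' @export
plot_volcano <- function(dams, lfc_threshold = 0.5, alpha = 0.05) {
  vd <- if ("neg_log10_p" %in% names(dams)) dams else volcano_data(dams)
  ggplot2::ggplot(vd, ggplot2::aes(
    x = .data$log2_fold_change, y = .data$neg_log10_p, colour = .data$status
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-lfc_threshold, lfc_threshold), linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(
      "significant-up" = "#c0392b", "significant-down" = "#2c5aa0",
      "not-significant" = "grey60"
    )) +
    ggplot2::facet_wrap(~comparison) +
    ggplot2::labs(
      x = expression(log[2] ~ "fold change"), y = expression(-log[10] ~ italic(p)),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' PCA score plot
#'
#' @param x A `pca_scores` object.
#' @param components Two component names to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pca_scores
#' @export
autoplot.pca_scores <- function(x, components = c("PC1", "PC2"), ...) {
  ve <- x$variance_explained[components]
  ggplot2::ggplot(x$scores, ggplot2::aes(
    x = .data[[components[1]]], y = .data[[components[2]]],
    colour = .data$condition
  )) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", components[1], 100 * ve[1]),
      y = sprintf("%s (%.1f%%)", components[2], 100 * ve[2])
    ) +
    ggplot2::theme_minimal()
}

#' Per-class DAM counts by direction
#'
#' @param x A `dam_summary`.
#' @param ... Unused.
#' @return A ggplot object (horizontal bars, faceted by comparison).
#' @method autoplot dam_summary
#' @export
autoplot.dam_summary <- function(x, ...) {
  ggplot2::ggplot(x$classes, ggplot2::aes(
    x = .data$n, y = .data$class, fill = .data$direction
  )) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_wrap(~comparison) +
    ggplot2::scale_fill_manual(values = c(up = "#c0392b", down = "#2c5aa0")) +
    ggplot2::labs(x = "significant DAMs", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
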