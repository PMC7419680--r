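#' Plot cluster assignments
#'
#' Adjusted CTLA-4 against the combined pathway score for one axis, colored
#' by cluster, with the median split lines.
#'
#' @param object an [assign_clusters()] result.
#' @param axis `"erk"` or `"akt"`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot cluster_assignment
#' @export
autoplot.cluster_assignment <- function(object, axis = c("erk", "akt"), ...) {
  axis <- match.arg(axis)
  score_col <- paste0(axis, "_score")
  cluster_col <- paste0(axis, "_cluster")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data[[score_col]],
                               y = .data$adjusted_ctla4,
                               colour = .data[[cluster_col]])) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = stats::median(object[[score_col]]),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = stats::median(object$adjusted_ctla4),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = paste(toupper(axis), "combined score"),
                  y = "adjusted CTLA-4", colour = "cluster") +
    ggplot2::theme_minimal()
}

#' Plot deconvolution fractions
#'
#' Stacked per-sample bars of relative immune cell-type proportions.
#'
#' @param object a [deconvolve()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot deconv_result
#' @export
autoplot.deconv_result <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$fraction,
                                     fill = .data$celltype)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "relative proportion", fill = "cell type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot a GSEA result table
#'
#' Bubble plot of normalized enrichment scores: point size |NES|, color FDR.
#'
#' @param object a [gsea()] result.
#' @param fdr_max only show sets at or below this FDR (default 0.25).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot gsea_table
#' @export
autoplot.gsea_table <- function(object, fdr_max = 0.25, ...) {
  shown <- dplyr::filter(object, .data$fdr < fdr_max)
  ggplot2::ggplot(shown,
                  ggplot2::aes(x = .data$nes,
                               y = stats::reorder(.data$set, .data$nes),
                               size = abs(.data$nes), colour = .data$fdr)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "NES", y = NULL, size = "|NES|", colour = "FDR") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
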