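#' Plot a precision-recall curve
#'
#' @param object A `pr_curve` from [precision_recall()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pr_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$recall,
                                       y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Recall", y = "Precision",
      title = sprintf("AUPR = %.3f (%d positives)",
                      sum(object$precision[object$hit]) /
                        attr(object, "n_positives"),
                      attr(object, "n_positives"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot the top genes of a search result
#'
#' Lollipop chart of the Stouffer-combined z-scores of the `n_top`
#' best-ranked genes, colored by whether they pass the configured FDR
#' threshold.
#'
#' @param object A [marker_search()] object.
#' @param n_top Number of genes shown (default 25).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.marker_search <- function(object, n_top = 25, ...) {
  top <- utils::head(object$pooled, n_top)
  top$gene_id <- factor(top$gene_id, levels = rev(top$gene_id))
  ggplot2::ggplot(top, ggplot2::aes(x = .data$combined_z,
                                    y = .data$gene_id,
                                    color = .data$predicted)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$combined_z,
                                       yend = .data$gene_id)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Combined z (Stouffer)", y = NULL,
                  color = sprintf("FDR ≤ %g",
                                  object$params$fdr_threshold)) +
    ggplot2::theme_minimal()
}

#' Plot a filtered singular-value spectrum
#'
#' Shows the raw singular values, the query-adaptive weights |w_k| and the
#' filtered spectrum sigma'_k = sigma_k^alpha |w_k|, with the Kaiser
#' truncation indicated. Accepts a filtered matrix from [svd_filter()] /
#' [filter_matrix()] (which carry a `"spectrum"` attribute) or the
#' spectrum tibble itself.
#'
#' @param x A filtered matrix or its spectrum tibble.
#' @return A ggplot.
#' @export
plot_filter_spectrum <- function(x) {
  spec <- if (is.matrix(x)) attr(x, "spectrum") else x
  stopifnot(is.data.frame(spec),
            all(c("k", "sigma", "w", "sigma_filtered") %in% colnames(spec)))
  long <- tidyr::pivot_longer(
    dplyr::mutate(spec, abs_w = abs(.data$w)),
    cols = c("sigma", "abs_w", "sigma_filtered"),
    names_to = "component", values_to = "value"
  )
  long$component <- factor(long$component,
                           levels = c("sigma", "abs_w", "sigma_filtered"),
                           labels = c("sigma", "|w|", "sigma'"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value,
                                     alpha = .data$retained)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~component, ncol = 1, scales = "free_y") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.3),
                                name = "retained") +
    ggplot2::labs(x = "Singular vector k", y = NULL) +
    ggplot2::theme_minimal()
}
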