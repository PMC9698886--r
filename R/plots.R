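# ggplot2 autoplot methods for the diagnostic objects.

#' Plot a fragment-length distribution
#'
#' Smoothed fragment-length histogram with detected nucleosome-band modes.
#'
#' @param object A `length_histogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.length_histogram <- function(object, ...) {
  ggplot2::ggplot(object$hist, ggplot2::aes(x = .data$length)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$count), width = 1,
                      fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), color = "steelblue") +
    ggplot2::geom_vline(data = object$modes,
                        ggplot2::aes(xintercept = .data$length),
                        linetype = "dashed", color = "firebrick") +
    ggplot2::labs(x = "fragment length (bp)", y = "fragments",
                  title = "Fragment-length distribution",
                  subtitle = sprintf("%d fragments; modes: %s",
                                     object$n_fragments,
                                     paste(object$modes$length, collapse = ", "))) +
    ggplot2::theme_minimal()
}

#' Plot a TSS enrichment profile
#'
#' @param object A `tss_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tss_profile <- function(object, ...) {
  ggplot2::ggplot(object$profile, ggplot2::aes(x = .data$offset)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_signal), color = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), color = "steelblue") +
    ggplot2::labs(x = "offset from TSS (bp)", y = "mean cut sites per TSS",
                  title = sprintf("TSS enrichment (score %.2f, %d genes)",
                                  object$enrichment_score, object$n_genes)) +
    ggplot2::theme_minimal()
}

#' Plot sample coordinates on the first two principal components
#'
#' @param object An `atac_pca`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.atac_pca <- function(object, ...) {
  ve <- object$variance_explained
  ggplot2::ggplot(object$coords,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               label = .data$sample)) +
    ggplot2::geom_point(size = 3, color = "steelblue") +
    ggplot2::geom_text(vjust = -1) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
                  y = sprintf("PC2 (%.1f%%)",
                              100 * (if (length(ve) >= 2) ve[2] else 0)),
                  title = "Sample PCA on most-variable atlas peaks") +
    ggplot2::theme_minimal()
}

#' MA-style plot of a peak classification
#'
#' Mean rlog accessibility against rlog fold change, colored by class, with
#' the classification thresholds drawn.
#'
#' @param object An `atac_classes` tibble from [classify_peaks()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.atac_classes <- function(object, ...) {
  thr <- attr(object, "threshold")
  pair <- attr(object, "pair")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$base_mean, y = .data$rlog_fc,
                               color = .data$class)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_hline(yintercept = c(-thr, thr), linetype = "dashed") +
    ggplot2::scale_color_manual(values = c(opening = "firebrick",
                                           closing = "steelblue",
                                           unchanged = "grey70")) +
    ggplot2::labs(x = "mean rlog accessibility", y = "rlog fold change",
                  title = sprintf("%s vs %s", pair[2], pair[1])) +
    ggplot2::theme_minimal()
}
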