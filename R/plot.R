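#' Plot an information footprint
#'
#' Bar plot of per-position mutual information, colored by the sign of the
#' expression shift (repressor-like vs activator/polymerase-like).
#'
#' @param object An `mpra_footprint` from [information_footprint()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mpra_footprint <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$mi,
                                       fill = .data$sign)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_fill_manual(values = c(`repressor-like` = "#B2182B",
                                          `activator-like` = "#2166AC",
                                          none = "grey70")) +
    ggplot2::labs(x = "position relative to TSS (bp)",
                  y = "mutual information (bits)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an expression-shift matrix
#'
#' Heatmap of per-base relative expression shifts; wild-type entries are
#' zero by construction.
#'
#' @param object An `mpra_shift_matrix` from [expression_shift_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mpra_shift_matrix <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$base,
                                       fill = .data$shift)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B") +
    ggplot2::labs(x = "position relative to TSS (bp)", y = NULL,
                  fill = "relative\nshift") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
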