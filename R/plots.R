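#' Differential-proximity heatmap
#'
#' One tile per ordered (center type, surround type) pair: fill is the
#' condition effect `beta` on the log B-ratio scale (positive = closer
#' in treatment), an asterisk marks FDR below `alpha`, and pairs without
#' an estimate are gray. Faceted by region when several are present.
#'
#' @param object A `diff_prox` object.
#' @param alpha FDR threshold for the significance mark (default 0.05).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.diff_prox <- function(object, alpha = 0.05, ...) {
  res <- tidy(object)
  res$sig <- !is.na(res$fdr) & res$fdr < alpha
  p <- ggplot2::ggplot(res, ggplot2::aes(x = .data$surround_type,
                                         y = .data$center_type,
                                         fill = .data$beta)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(data = res[res$sig, , drop = FALSE],
                       ggplot2::aes(label = "*"), size = 5, vjust = 0.75) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0,
                                  na.value = "grey80",
                                  name = expression(beta)) +
    ggplot2::labs(x = "surround type (B)", y = "center type (A)",
                  title = "Differential proximity (treatment vs reference)",
                  subtitle = paste0("log(B-ratio + ", object$spec$offset,
                                    ") ~ condition + (1 | sample); * FDR < ",
                                    alpha)) +
    ggplot2::theme_minimal()
  if (length(unique(res$region)) > 1) {
    p <- p + ggplot2::facet_wrap(~region)
  }
  p
}

#' Map of a simulated or measured tissue
#'
#' Cell centroids colored by type, faceted by sample.
#'
#' @param cells A cell table.
#' @param type_level Column used for the color (default `"cell_type"`).
#' @return A ggplot.
#' @export
plot_tissue <- function(cells, type_level = "cell_type") {
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$x, y = .data$y,
                                      color = .data[[type_level]])) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~sample_id) +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", color = type_level) +
    ggplot2::theme_minimal()
}

#' QC cascade waterfall
#'
#' Cells surviving each stage of the QC cascade.
#'
#' @param report A `qc_report` from [run_qc()].
#' @return A ggplot.
#' @export
plot_qc_report <- function(report) {
  df <- tibble(stage = factor(report$stage, levels = report$stage),
               n_out = report$n_out, n_removed = report$n_removed)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$n_out)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = paste0("-", .data$n_removed)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "cells surviving",
                  title = "QC cascade") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
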