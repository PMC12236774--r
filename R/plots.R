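#' Plot parameter-selection curves
#'
#' One panel per metric, the smoothed full-set-scaled value against
#' log10(d_max), coloured by method.
#'
#' @param curve A [build_metric_curves()] result.
#' @param value_col Column to plot (default `"scaled"`).
#' @return A ggplot object.
#' @export
plot_metric_curves <- function(curve, value_col = "scaled") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ggplot2::ggplot(curve, ggplot2::aes(x = log10(.data$d_max),
                                      y = .data[[value_col]],
                                      colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = expression(log[10](d[max]~"(bp)")),
                  y = "metric (full-set scaled)") +
    ggplot2::theme_bw()
}

#' Plot per-sample precision
#'
#' Samples on the x axis in descending PPV order, stacked TP/FP counts;
#' the layout used to spot the poorly performing samples that concentrate
#' false positives.
#'
#' @param sample_table Output of [samplewise_ppv()].
#' @return A ggplot object.
#' @export
plot_samplewise_ppv <- function(sample_table) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  tab <- sample_table
  tab$sample_id <- factor(tab$sample_id, levels = tab$sample_id)
  long <- tidyr::pivot_longer(tab, dplyr::all_of(c("tp", "fp")),
                              names_to = "class", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$count,
                                     fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(tp = "#2166ac", fp = "#b2182b")) +
    ggplot2::labs(x = "sample (descending PPV)", y = "CNV calls") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
}
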