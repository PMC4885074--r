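#' Plot the coverage-binned reliability profile of a cross-validation run
#'
#' Bar chart of per-bin accuracy with the per-bin prediction count overlaid
#' as a line, over right-closed coverage bins of width 0.1 (last bin
#' open-ended). Bars are shaded by confidence tier: poorly reliable
#' (coverage <= 0.1), reliable, and highly reliable (> 0.8).
#'
#' @param object A `phagehost_cv` object.
#' @param bin_width Coverage bin width (default 0.1).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.phagehost_cv <- function(object, bin_width = 0.1, ...) {
  tab <- coverage_binned_accuracy(object$records, bin_width = bin_width)
  tab$tier <- ifelse(tab$lower >= 0.8, "highly reliable",
                     ifelse(tab$lower >= 0.1, "reliable", "poorly reliable"))
  scale <- max(tab$n, 1L)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$bin)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$accuracy, fill = .data$tier),
                      na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$n / scale, group = 1),
                       linewidth = 0.6) +
    ggplot2::geom_point(ggplot2::aes(y = .data$n / scale)) +
    ggplot2::scale_y_continuous(
      "accuracy", limits = c(0, 1),
      sec.axis = ggplot2::sec_axis(~ . * scale, name = "predictions")
    ) +
    ggplot2::scale_fill_manual(values = c(
      "poorly reliable" = "grey70", "reliable" = "#74c476",
      "highly reliable" = "#006d2c"
    )) +
    ggplot2::labs(x = "coverage bin", fill = NULL,
                  title = sprintf("Accuracy by best-hit coverage (%s level)",
                                  object$level)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a nested grid-search accuracy curve
#'
#' Accuracy versus parameter value, one curve per tripartite set, with the
#' per-set 99%-of-maximum range shaded.
#'
#' @param object A `phagehost_grid` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.phagehost_grid <- function(object, ...) {
  res <- object$results
  res$set <- factor(res$set)
  opt <- object$optimum
  opt$set <- factor(opt$set)
  ggplot2::ggplot(res, ggplot2::aes(x = .data$value, y = .data$accuracy,
                                    colour = .data$set)) +
    ggplot2::geom_rect(
      data = opt,
      ggplot2::aes(xmin = .data$range_low, xmax = .data$range_high,
                   fill = .data$set),
      ymin = -Inf, ymax = Inf, alpha = 0.08, inherit.aes = FALSE
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = object$param, y = "inner-CV accuracy",
                  colour = "tripartite set", fill = "tripartite set",
                  title = sprintf("Nested grid search over %s (%s level)",
                                  object$param, object$level)) +
    ggplot2::theme_minimal()
}

#' Plot a genome-truncation experiment
#'
#' Accuracy over predicted queries and fraction of queries with a
#' prediction, against the genome fraction used as query.
#'
#' @param truncation Tibble from [truncation_experiment()].
#' @return A ggplot object.
#' @export
plot_truncation <- function(truncation) {
  long <- tidyr::pivot_longer(
    truncation[, c("fraction", "prop_predicted", "accuracy")],
    cols = c("prop_predicted", "accuracy"),
    names_to = "measure", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$fraction, y = .data$value,
                                     colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = truncation$fraction) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "genome fraction used as query", y = NULL,
                  colour = NULL,
                  title = "Robustness to genome incompleteness") +
    ggplot2::theme_minimal()
}
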