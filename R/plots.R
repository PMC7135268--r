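# ggplot2 visualizations of an experiment report: median AUC with IQR error
# bars per model (train vs test), and mean +/- SD normalized feature
# ratings per model.

#' Plot model performance (median AUC with IQR error bars)
#'
#' @param report An [run_experiment()] report.
#' @return A ggplot object.
#' @export
plot_performance <- function(report) {
  stopifnot(inherits(report, "experiment_report"))
  df <- report$performance
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$median_auc,
                                   color = .data$partition)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$median_auc - .data$iqr / 2,
                   ymax = .data$median_auc + .data$iqr / 2),
      position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = NULL, y = "AUC (median ± IQR/2 over shuffles)",
                  color = "partition") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot feature-importance ratings (mean +/- SD over shuffles)
#'
#' @param report An [run_experiment()] report with importance summaries.
#' @return A ggplot object.
#' @export
plot_importance <- function(report) {
  stopifnot(inherits(report, "experiment_report"))
  if (is.null(report$importance)) {
    abort("The report contains no importance summaries.")
  }
  df <- report$importance
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature, y = .data$mean_rating,
                                   fill = .data$model)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$mean_rating - .data$sd_rating, 0),
                   ymax = .data$mean_rating + .data$sd_rating),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25) +
    ggplot2::labs(x = NULL, y = "normalized rating (mean ± SD)",
                  fill = "model") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' @rdname plot_performance
#' @param object An `experiment_report`.
#' @param type `"performance"` or `"importance"`.
#' @param ... Unused.
#' @export
autoplot.experiment_report <- function(object, type = c("performance",
                                                        "importance"), ...) {
  switch(match.arg(type),
         performance = plot_performance(object),
         importance = plot_importance(object))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
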