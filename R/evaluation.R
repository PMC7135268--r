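# Performance assessment: rank-based (Mann-Whitney) ROC AUC with ties
# counted 1/2, and median/IQR summaries across shuffles.

#' Rank-based ROC AUC
#'
#' The probability that a random positive is scored above a random
#' negative, with ties counted 1/2 (midranks) — equivalent to the
#' Mann-Whitney U statistic scaled to `[0, 1]`.
#'
#' @param scores Numeric scores (e.g. predicted probabilities); finite.
#' @param labels Binary 0/1 labels; both classes must be present.
#' @return A single AUC value in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
roc_auc <- function(scores, labels) {
  assert_binary(labels, "labels")
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` must have equal length.")
  }
  if (!all(is.finite(scores))) abort("`scores` must be finite.")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("Both classes must be present.")
  r <- rank(scores)   # midranks handle ties with the 1/2 convention
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Summarize per-shuffle performance
#'
#' Medians and interquartile ranges of AUC per model and partition across
#' shuffles (linear-interpolation quantiles).
#'
#' @param results Tibble with columns `shuffle`, `model`, `partition`,
#'   `auc` (one row per shuffle x model x partition).
#' @return A tibble with columns `model`, `partition`, `median_auc`, `iqr`,
#'   `n_shuffles`.
#' @export
summarize_performance <- function(results) {
  stopifnot(is.data.frame(results))
  if (nrow(results) == 0) abort("Need at least one shuffle's results.")
  needed <- c("model", "partition", "auc")
  if (!all(needed %in% names(results))) {
    abort("`results` must have columns model, partition, auc.")
  }
  dplyr::summarise(
    dplyr::group_by(results, .data$model, .data$partition),
    median_auc = median(.data$auc),
    iqr = unname(diff(quantile(.data$auc, c(0.25, 0.75), type = 7))),
    n_shuffles = dplyr::n(),
    .groups = "drop")
}
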