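# Importance vectors and the cross-model unit-sum normalization: per shuffle,
# take absolute values and divide by their sum (range [0,1], sum 1); across
# shuffles, report the per-feature mean and standard deviation.

#' Construct an importance vector
#'
#' @param scores Named numeric scores per feature (raw, signed).
#' @param model Model family the scores came from.
#' @param method Attribution method (`"coefficients"`, `"shap"`,
#'   `"deep_taylor"`).
#' @param normalized Whether the scores are already unit-sum normalized.
#' @return A named numeric vector of class `importance_vector`.
#' @export
new_importance <- function(scores, model = NA_character_,
                           method = NA_character_, normalized = FALSE) {
  structure(as.numeric(scores),
            names = names(scores),
            model = model, method = method, normalized = normalized,
            class = "importance_vector")
}

#' @export
print.importance_vector <- function(x, ...) {
  cat("<importance_vector>", attr(x, "model"), "/", attr(x, "method"),
      if (isTRUE(attr(x, "normalized"))) "(normalized)" else "(raw)", "\n")
  print(signif(stats::setNames(as.numeric(x), names(x)), 4))
  invisible(x)
}

#' @export
tidy.importance_vector <- function(x, ...) {
  tibble::tibble(feature = names(x) %||% paste0("x", seq_along(x)),
                 score = as.numeric(x),
                 model = attr(x, "model"), method = attr(x, "method"),
                 normalized = attr(x, "normalized"))
}

#' Raw importance of a linear model: its coefficients
#'
#' On standardized features the coefficient magnitudes are directly
#' comparable; signs are retained here and dropped at normalization.
#'
#' @param params A fitted `linear_model_params` (intercept excluded).
#' @return An `importance_vector` (raw).
#' @export
linear_importance <- function(params) {
  if (!inherits(params, "linear_model_params")) {
    abort("`params` must be a fitted linear model.")
  }
  new_importance(params$coefficients, model = params$kind,
                 method = "coefficients")
}

#' Unit-sum (L1) normalization of one raw importance vector
#'
#' Takes absolute values and divides by their sum, confining every score to
#' `[0, 1]` with total 1.
#'
#' @param raw Numeric vector of raw scores with at least one nonzero entry.
#' @return A normalized `importance_vector`.
#' @export
l1_normalize <- function(raw) {
  a <- abs(as.numeric(raw))
  s <- sum(a)
  if (s == 0) abort("Cannot normalize an all-zero importance vector.")
  new_importance(stats::setNames(a / s, names(raw)),
                 model = attr(raw, "model") %||% NA_character_,
                 method = attr(raw, "method") %||% NA_character_,
                 normalized = TRUE)
}

#' Normalize raw importance vectors across shuffles
#'
#' Each shuffle's raw vector is unit-sum normalized ([l1_normalize()]);
#' per-feature means and standard deviations across shuffles are reported.
#' All-zero raw vectors are excluded with a warning.
#'
#' @param raw_vectors List of raw importance vectors (one per shuffle),
#'   all over the same features.
#' @return A tibble with columns `feature`, `mean_rating`, `sd_rating`,
#'   `n_shuffles`; the matrix of per-shuffle normalized scores is attached
#'   as attribute `"normalized"`.
#' @export
normalize_importance <- function(raw_vectors) {
  stopifnot(is.list(raw_vectors), length(raw_vectors) >= 1)
  keep <- vapply(raw_vectors, function(v) sum(abs(as.numeric(v))) > 0,
                 logical(1))
  if (!all(keep)) {
    warn(sprintf("%d all-zero importance vector(s) excluded.", sum(!keep)))
  }
  raw_vectors <- raw_vectors[keep]
  if (!length(raw_vectors)) abort("All importance vectors were zero.")
  mat <- do.call(rbind, lapply(raw_vectors,
                               function(v) as.numeric(l1_normalize(v))))
  colnames(mat) <- names(raw_vectors[[1]])
  out <- tibble::tibble(
    feature = colnames(mat),
    mean_rating = unname(colMeans(mat)),
    sd_rating = unname(apply(mat, 2, function(col) {
      if (nrow(mat) > 1) sd(col) else 0
    })),
    n_shuffles = nrow(mat))
  attr(out, "normalized") <- mat
  out
}
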