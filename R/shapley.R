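# Exact Shapley values by full subset enumeration with an interventional
# value function: f_S(x_S) is the mean model output over background rows
# whose features in S are replaced by x's values.  Weights are
# |S|! (|F| - |S| - 1)! / |F|!, exactly the classical formula.

#' Exact Shapley values for one observation
#'
#' Enumerates all `2^|F|` feature subsets.  The value of a coalition `S` is
#' the mean of `predict_fun` over the background rows with the features in
#' `S` replaced by the observation's values (interventional marginalization).
#' The Shapley value of feature `i` is the classically weighted average of
#' its marginal contributions over all subsets not containing `i`.
#'
#' @param predict_fun Function taking a numeric feature matrix and
#'   returning a numeric prediction per row (e.g. a probability).
#' @param x A single observation: numeric vector (or 1-row matrix) with the
#'   model's features.
#' @param background Numeric matrix of background rows used to marginalize
#'   absent features; non-empty.
#' @param features Optional indices of the features to attribute over
#'   (default: all columns).
#' @return Named numeric vector of Shapley values, one per feature, with
#'   attributes `fx` (the full-coalition value) and `f0` (the empty-coalition
#'   baseline), so efficiency `sum(phi) = fx - f0` can be checked directly.
#' @export
exact_shapley <- function(predict_fun, x, background, features = NULL) {
  if (is.matrix(x)) x <- drop(x)
  background <- as_feature_matrix(background)
  if (nrow(background) == 0) abort("`background` must be non-empty.")
  p_all <- ncol(background)
  if (length(x) != p_all) abort("`x` length must match `background` columns.")
  features <- features %||% seq_len(p_all)
  p <- length(features)
  if (p > 15) {
    abort(paste("Exact enumeration is limited to 15 features (2^|F|",
                "coalitions); use a sampling approximation for more."))
  }
  n_mask <- 2^p
  nb <- nrow(background)
  # coalition values: one predict call per subset on the modified background
  v <- numeric(n_mask)
  for (mask in 0:(n_mask - 1)) {
    Xb <- background
    if (mask > 0) {
      in_s <- features[bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) != 0L]
      Xb[, in_s] <- matrix(x[in_s], nb, length(in_s), byrow = TRUE)
    }
    v[mask + 1] <- mean(predict_fun(Xb))
  }
  sizes <- vapply(0:(n_mask - 1), function(m) sum(bitwAnd(m, bitwShiftL(
    1L, 0:(p - 1))) != 0L), numeric(1))
  # w[s + 1] = s! (p - s - 1)! / p!
  wts <- exp(lgamma(0:(p - 1) + 1) + lgamma(p - (0:(p - 1))) - lgamma(p + 1))
  phi <- numeric(p)
  for (i in seq_len(p)) {
    bit <- bitwShiftL(1L, i - 1L)
    without <- which(bitwAnd(0:(n_mask - 1), bit) == 0L)
    s <- sizes[without]
    phi[i] <- sum(wts[s + 1] * (v[without + bit] - v[without]))
  }
  names(phi) <- colnames(background)[features]
  attr(phi, "fx") <- v[n_mask]
  attr(phi, "f0") <- v[1]
  phi
}

#' Per-observation Shapley values over a set of observations
#'
#' @inheritParams exact_shapley
#' @param X Matrix of observations (rows) to explain.
#' @return Matrix observations x features of Shapley values.
#' @export
shapley_matrix <- function(predict_fun, X, background, features = NULL) {
  X <- as_feature_matrix(X)
  out <- t(vapply(seq_len(nrow(X)), function(i) {
    as.numeric(exact_shapley(predict_fun, X[i, ], background, features))
  }, numeric(length(features %||% seq_len(ncol(background))))))
  colnames(out) <- colnames(background)[features %||% seq_len(ncol(background))]
  out
}

#' Aggregate per-observation Shapley values into a raw importance vector
#'
#' The raw score of a feature is the mean signed Shapley value across
#' observations; absolute values are taken later, at normalization.
#'
#' @param per_observation_phis Matrix of Shapley values, observations x
#'   features.
#' @return An `importance_vector` (raw).
#' @export
aggregate_shap <- function(per_observation_phis) {
  m <- as.matrix(per_observation_phis)
  if (nrow(m) < 1) abort("Need at least one observation's Shapley values.")
  new_importance(colMeans(m), model = "gbdt", method = "shap")
}
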