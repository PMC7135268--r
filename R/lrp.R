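# Layer-wise relevance propagation with the alpha = 1, beta = 0 (z+) rule —
# the deep Taylor decomposition for rectifier networks.  Relevance starts at
# an output neuron (by default the bad-outcome neuron, with value equal to
# the predicted bad-outcome probability, so every observation decomposes
# the same quantity) and is redistributed backwards proportionally to
# positive-weighted activations:  r_j = sum_k [a_j w+_jk / sum_j a_j w+_jk] r_k.
# Bias terms do not enter the denominators, so each propagation step
# conserves the total relevance exactly (zero-denominator neurons pass on
# zero relevance).

#' Deep Taylor decomposition (LRP z+ rule) for one observation
#'
#' @param mlp A fitted [fit_mlp()] network.
#' @param x A single observation (numeric vector).
#' @param class_neuron Which output neuron seeds the relevance: `"bad"`
#'   (default) always decomposes the bad-outcome probability `P(O=1|x)`,
#'   so every observation's relevances explain the same predicted
#'   quantity; `"predicted"` seeds at the argmax class instead.
#' @return A list of class `relevance_map` with elements `input` (per-input
#'   relevance, named), `hidden`, `output` (the seeded relevance),
#'   `seed_class` (0 = good, 1 = bad outcome) and `predicted_class`.
#' @export
lrp_deep_taylor <- function(mlp, x, class_neuron = c("bad", "predicted")) {
  class_neuron <- match.arg(class_neuron)
  stopifnot(inherits(mlp, "mlp_params"))
  if (is.matrix(x)) x <- drop(x)
  if (length(x) != nrow(mlp$W1)) {
    abort("`x` length does not match the network's input size.")
  }
  fw <- mlp_forward(mlp, matrix(x, 1), inference = TRUE)
  if (!all(is.finite(fw$H)) || !all(is.finite(fw$P))) {
    abort("Non-finite activations in the forward pass.")
  }
  pred <- which.max(fw$P[1, ])
  k_star <- if (class_neuron == "bad") 2L else pred
  r_out <- fw$P[1, k_star]
  a_hidden <- fw$H[1, ]                    # inference-mode activations
  # output -> hidden
  w2p <- pmax(mlp$W2[, k_star], 0)
  z <- a_hidden * w2p
  denom <- sum(z)
  r_hidden <- if (denom > 0) z / denom * r_out else numeric(length(z))
  # hidden -> input
  W1p <- pmax(mlp$W1, 0)                   # inputs x hidden
  Z <- x * W1p                             # z_ij = a_i w+_ij
  denoms <- colSums(Z)
  shares <- sweep(Z, 2, ifelse(denoms != 0, denoms, Inf), "/")
  r_input <- drop(shares %*% r_hidden)
  names(r_input) <- mlp$features
  structure(list(input = r_input, hidden = r_hidden, output = r_out,
                 seed_class = k_star - 1L, predicted_class = pred - 1L),
            class = "relevance_map")
}

#' @export
print.relevance_map <- function(x, ...) {
  cat("<relevance_map> output relevance", signif(x$output, 4),
      "| predicted class", x$predicted_class, "\n")
  print(signif(x$input, 4))
  invisible(x)
}

#' Input relevances for a set of observations
#'
#' @param mlp A fitted [fit_mlp()] network.
#' @param X Matrix of observations.
#' @inheritParams lrp_deep_taylor
#' @return Matrix observations x input features of relevances.
#' @export
lrp_matrix <- function(mlp, X, class_neuron = c("bad", "predicted")) {
  class_neuron <- match.arg(class_neuron)
  X <- as_feature_matrix(X)
  out <- t(vapply(seq_len(nrow(X)),
                  function(i) lrp_deep_taylor(mlp, X[i, ], class_neuron)$input,
                  numeric(nrow(mlp$W1))))
  colnames(out) <- mlp$features
  out
}

#' Confidence-weighted feature rating
#'
#' Aggregates per-observation relevances `r_i(f)` into
#' `R(f) = (1/N) * sum_i theta_i * r_i(f)` with
#' `theta_i = y_i * P_i + (1 - y_i) * (1 - P_i)`: observations the model
#' predicts confidently *and correctly* weigh most.
#'
#' @param relevance_per_obs Matrix observations x features.
#' @param predicted_prob Predicted bad-outcome probabilities, in `[0, 1]`.
#' @param labels Binary 0/1 outcome labels.
#' @return An `importance_vector` (raw).
#' @export
confidence_weighted_rating <- function(relevance_per_obs, predicted_prob,
                                       labels) {
  R <- as.matrix(relevance_per_obs)
  if (nrow(R) != length(predicted_prob) || nrow(R) != length(labels)) {
    abort("Relevances, probabilities and labels must have aligned lengths.")
  }
  assert_binary(labels, "labels")
  if (any(predicted_prob < 0 | predicted_prob > 1)) {
    abort("`predicted_prob` must lie in [0, 1].")
  }
  theta <- labels * predicted_prob + (1 - labels) * (1 - predicted_prob)
  new_importance(colMeans(theta * R), model = "mlp", method = "deep_taylor")
}
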