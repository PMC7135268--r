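# One-hidden-layer multilayer perceptron with a rectifier hidden activation
# and a 2-way softmax output, trained by minibatch SGD on binary
# cross-entropy plus an L1 weight penalty, with dropout on the hidden layer
# during training and (1 - DR) output weighting at inference.

#' MLP hyperparameters
#'
#' @param hidden_units Number of hidden-layer neurons `M`.
#' @param learning_rate SGD step size.
#' @param batch_size Minibatch size.
#' @param dropout_rate Probability `DR` of dropping each hidden unit during
#'   training; hidden outputs are weighted by `1 - DR` at inference.
#' @param l1_ratio Coefficient of the L1 penalty on the weight matrices.
#' @param epochs Maximum training epochs.
#' @param patience Early stop after this many epochs without a relative
#'   training-loss improvement of at least `tol`.
#' @param tol Relative loss-improvement threshold for the early stop.
#' @return A list of class `mlp_hyper`.
#' @export
mlp_hyper <- function(hidden_units = 10, learning_rate = 0.01,
                      batch_size = 16, dropout_rate = 0.1, l1_ratio = 1e-4,
                      epochs = 300, patience = 20, tol = 1e-6) {
  structure(list(hidden_units = hidden_units, learning_rate = learning_rate,
                 batch_size = batch_size, dropout_rate = dropout_rate,
                 l1_ratio = l1_ratio, epochs = epochs, patience = patience,
                 tol = tol),
            class = "mlp_hyper")
}

relu <- function(x) pmax(x, 0)

softmax2 <- function(L) {
  m <- pmax(L[, 1], L[, 2])
  e1 <- exp(L[, 1] - m); e2 <- exp(L[, 2] - m)
  unname(cbind(e1, e2) / (e1 + e2))
}

# forward pass; class columns are (good, bad) = (y = 0, y = 1)
mlp_forward <- function(params, X, dropout_mask = NULL, inference = TRUE) {
  H <- relu(sweep(X %*% params$W1, 2, params$b1, "+"))
  if (!is.null(dropout_mask)) {
    H <- sweep(H, 2, dropout_mask, "*")
  } else if (inference && params$dropout_rate > 0) {
    H <- H * (1 - params$dropout_rate)
  }
  L <- sweep(H %*% params$W2, 2, params$b2, "+")
  list(H = H, logits = L, P = softmax2(L))
}

mlp_loss <- function(P, y, params, l1) {
  p1 <- pmin(pmax(P[, 2], 1e-12), 1 - 1e-12)
  bce <- -mean(y * log(p1) + (1 - y) * log(1 - p1))
  bce + l1 * (sum(abs(params$W1)) + sum(abs(params$W2)))
}

# analytic gradients for one (mini)batch, given the dropout mask applied
mlp_gradients <- function(params, X, y, dropout_mask = NULL) {
  n <- nrow(X)
  fw <- mlp_forward(params, X, dropout_mask = dropout_mask,
                    inference = FALSE)
  Y <- cbind(1 - y, y)
  dL <- (fw$P - Y) / n
  gW2 <- t(fw$H) %*% dL + params$l1_ratio * sign(params$W2)
  gb2 <- colSums(dL)
  dH <- dL %*% t(params$W2)
  if (!is.null(dropout_mask)) dH <- sweep(dH, 2, dropout_mask, "*")
  dH <- dH * (fw$H > 0)
  gW1 <- t(X) %*% dH + params$l1_ratio * sign(params$W1)
  gb1 <- colSums(dH)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
       loss = mlp_loss(fw$P, y, params, params$l1_ratio))
}

#' Fit a one-hidden-layer MLP
#'
#' Minibatch SGD on binary cross-entropy with an L1 weight penalty.
#' Dropout masks the hidden layer during training; inference weights the
#' hidden outputs by `1 - dropout_rate` (expected-value rule).  Training is
#' fully reproducible from `seed` and stops early when the epoch training
#' loss stalls.
#'
#' @inheritParams fit_glm
#' @param hyper An [mlp_hyper()] configuration.
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @return An object of class `mlp_params`.
#' @export
fit_mlp <- function(X, y, hyper = mlp_hyper(), seed = 1L) {
  X <- check_xy(X, y)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X); p <- ncol(X); M <- hyper$hidden_units
  params <- with_seed(seed, list(
    W1 = matrix(rnorm(p * M, sd = sqrt(2 / p)), p, M),
    b1 = numeric(M),
    W2 = matrix(rnorm(M * 2, sd = sqrt(2 / M)), M, 2),
    b2 = numeric(2),
    dropout_rate = hyper$dropout_rate, l1_ratio = hyper$l1_ratio,
    features = colnames(X), hyper = hyper, seed = seed))
  lr <- hyper$learning_rate
  best <- Inf; stall <- 0L; history <- numeric(0)
  with_seed(derive_seed(seed, 1L, stream = 3L), {
    for (epoch in seq_len(hyper$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = hyper$batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + hyper$batch_size - 1, n)]
        mask <- if (hyper$dropout_rate > 0) {
          as.numeric(runif(M) >= hyper$dropout_rate)
        } else NULL
        gr <- mlp_gradients(params, X[idx, , drop = FALSE], y[idx],
                            dropout_mask = mask)
        if (!is.finite(gr$loss)) {
          abort("Non-finite training loss: MLP optimization halted.")
        }
        params$W1 <- params$W1 - lr * gr$W1
        params$b1 <- params$b1 - lr * gr$b1
        params$W2 <- params$W2 - lr * gr$W2
        params$b2 <- params$b2 - lr * gr$b2
      }
      fw <- mlp_forward(params, X, inference = TRUE)
      ep_loss <- mlp_loss(fw$P, y, params, hyper$l1_ratio)
      history[epoch] <- ep_loss
      if (!is.finite(best) || ep_loss < best - hyper$tol * max(1, best)) {
        best <- ep_loss; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= hyper$patience) break
      }
    }
  })
  params$train_loss <- history
  structure(params, class = c("mlp_params", "stroke_model"))
}

#' @export
predict_proba.mlp_params <- function(model, X, ...) {
  X <- as_feature_matrix(X)
  if (ncol(X) != nrow(model$W1)) {
    abort("`X` column count does not match the network's input size.")
  }
  mlp_forward(model, X, inference = TRUE)$P[, 2]
}

#' @export
print.mlp_params <- function(x, ...) {
  cat("<mlp_params>", nrow(x$W1), "inputs ->", ncol(x$W1),
      "hidden (rectifier) -> 2 softmax | dropout", x$dropout_rate,
      "| L1", x$l1_ratio, "\n")
  invisible(x)
}

#' @export
glance.mlp_params <- function(x, ...) {
  tibble::tibble(hidden_units = ncol(x$W1),
                 dropout_rate = x$dropout_rate, l1_ratio = x$l1_ratio,
                 epochs_run = length(x$train_loss),
                 final_train_loss = if (length(x$train_loss))
                   x$train_loss[length(x$train_loss)] else NA_real_)
}
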