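# Linear model family: unregularized logistic regression (GLM) by maximum
# likelihood, the Lasso (L1, parameterized by the inverse strength C), and
# the elastic net (mixed L1/L2, parameterized by alpha and l1_ratio).
# Penalized fits are delegated to glmnet's coordinate-descent solver with
# the penalties mapped onto its lambda/alpha parameterization; intercepts
# are always unpenalized.

new_linear_model <- function(kind, coefficients, intercept, hyper = list(),
                             converged = TRUE) {
  structure(list(kind = kind,
                 coefficients = coefficients,
                 intercept = unname(intercept),
                 hyper = hyper, converged = converged),
            class = c("linear_model_params", "stroke_model"))
}

#' @export
print.linear_model_params <- function(x, ...) {
  cat("<linear_model_params>", x$kind, "|",
      length(x$coefficients), "coefficients | intercept",
      signif(x$intercept, 4), "\n")
  invisible(x)
}

check_xy <- function(X, y) {
  X <- as_feature_matrix(X)
  assert_binary(y)
  if (anyNA(X)) abort("`X` must be complete (impute before fitting).")
  if (nrow(X) != length(y)) abort("`X` rows and `y` length differ.")
  if (length(unique(y)) < 2) abort("Both outcome classes must be present.")
  X
}

#' Fit an unregularized logistic regression (GLM)
#'
#' Maximum-likelihood logistic regression of the bad-outcome label on the
#' standardized features, with an unpenalized intercept.  Perfect or
#' quasi-perfect separation yields a capped-iteration fit flagged with
#' `converged = FALSE`.
#'
#' @param X Complete numeric feature matrix (standardized).
#' @param y Binary 0/1 outcome vector.
#' @return A `linear_model_params` object.
#' @export
fit_glm <- function(X, y) {
  X <- check_xy(X, y)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  fit <- suppressWarnings(
    stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                   family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10,
                                                maxit = 100)))
  beta <- fit$coefficients
  separated <- !fit$converged || any(fit$fitted.values > 1 - 1e-10) ||
    any(fit$fitted.values < 1e-10)
  if (separated) {
    warn("Possible separation: GLM fit capped; coefficients may be unstable.")
  }
  new_linear_model("glm", beta[-1], beta[1], converged = !separated)
}

# glmnet backend shared by the two penalized fits; lambda is the glmnet-scale
# penalty multiplier of alpha*||b||_1 + (1-alpha)/2*||b||_2^2
fit_glmnet_logistic <- function(X, y, lambda, alpha_mix, hyper, kind) {
  X <- check_xy(X, y)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  # a short warm-start path down to the target lambda stabilizes small-lambda
  # solutions; coefficients are read off at the target exactly
  lam_path <- sort(unique(c(lambda * c(1000, 100, 10, 3), lambda)),
                   decreasing = TRUE)
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = alpha_mix,
                        lambda = lam_path, standardize = FALSE,
                        intercept = TRUE, thresh = 1e-14, maxit = 1e6)
  cf <- as.matrix(stats::coef(fit, s = lambda, exact = TRUE, x = X, y = y))
  new_linear_model(kind, stats::setNames(cf[-1, 1], rownames(cf)[-1]),
                   cf[1, 1], hyper = hyper)
}

#' Fit the Lasso (L1-penalized logistic regression)
#'
#' Minimizes the negative log-likelihood plus an L1 penalty whose strength
#' is parameterized by the inverse regularizer multiplier `C` (larger `C`
#' means weaker penalty; `C -> Inf` recovers the unregularized GLM).
#'
#' @inheritParams fit_glm
#' @param C Inverse regularization strength, > 0.
#' @return A `linear_model_params` object.
#' @export
fit_lasso <- function(X, y, C) {
  if (C <= 0) abort("`C` must be positive.")
  n <- NROW(X)
  fit_glmnet_logistic(X, y, lambda = 1 / (n * C), alpha_mix = 1,
                      hyper = list(C = C), kind = "lasso")
}

#' Fit the elastic net (mixed L1/L2-penalized logistic regression)
#'
#' Minimizes the mean negative log-likelihood plus
#' `alpha * (l1_ratio * ||b||_1 + (1 - l1_ratio)/2 * ||b||_2^2)`.
#' `l1_ratio = 1` recovers the Lasso at the corresponding strength.
#'
#' @inheritParams fit_glm
#' @param alpha Overall penalty strength, >= 0.
#' @param l1_ratio Mixing weight of the L1 term, in `[0, 1]`.
#' @return A `linear_model_params` object.
#' @export
fit_elastic_net <- function(X, y, alpha, l1_ratio) {
  if (alpha < 0) abort("`alpha` must be non-negative.")
  if (l1_ratio < 0 || l1_ratio > 1) abort("`l1_ratio` must lie in [0, 1].")
  if (alpha == 0) return(fit_glm(X, y))
  fit_glmnet_logistic(X, y, lambda = alpha, alpha_mix = l1_ratio,
                      hyper = list(alpha = alpha, l1_ratio = l1_ratio),
                      kind = "elastic_net")
}

#' Predicted bad-outcome probabilities
#'
#' @param model A fitted model (`linear_model_params`, `tree_ensemble` or
#'   `mlp_params`).
#' @param X Numeric feature matrix with the model's feature count.
#' @param ... Unused.
#' @return Probability vector in `[0, 1]`.
#' @export
predict_proba <- function(model, X, ...) UseMethod("predict_proba")

#' @export
predict_proba.linear_model_params <- function(model, X, ...) {
  X <- as_feature_matrix(X)
  if (ncol(X) != length(model$coefficients)) {
    abort("`X` column count does not match the model's feature count.")
  }
  plogis(drop(model$intercept + X %*% model$coefficients))
}

#' @export
tidy.linear_model_params <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", names(x$coefficients)),
                 estimate = c(x$intercept, unname(x$coefficients)))
}

#' @export
glance.linear_model_params <- function(x, ...) {
  tibble::tibble(kind = x$kind, n_features = length(x$coefficients),
                 converged = x$converged)
}
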