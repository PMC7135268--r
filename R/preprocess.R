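# Data preparation: mRS dichotomization, 4:1 train/test split, train-derived
# mean/mode imputation + zero-mean unit-variance scaling, class-balance
# subsampling, and the variance-inflation-factor multicollinearity screen.

#' Dichotomize modified Rankin Scale outcomes
#'
#' mRS 0-2 is a good outcome (label 0); mRS 3-6 is a bad outcome (label 1).
#'
#' @param mrs Integer vector with entries in `{0, ..., 6}`.
#' @return Integer 0/1 vector; 1 = bad outcome.
#' @export
#' @examples
#' dichotomize_mrs(c(0, 2, 3, 6))
dichotomize_mrs <- function(mrs) {
  if (anyNA(mrs) || !all(mrs %in% 0:6)) {
    abort("All mRS values must lie in {0, ..., 6} (no missing values).")
  }
  as.integer(mrs >= 3)
}

#' Random 4:1 train/test split
#'
#' A seeded uniform permutation of the rows; the test set takes
#' `round(n_rows / 5)` rows, matching the study's 4:1 ratio.
#'
#' @param n_rows Number of rows (>= 5).
#' @param seed Integer seed.
#' @return A list of class `split_indices` with sorted integer vectors
#'   `train` and `test` and the `seed`.
#' @export
split_train_test <- function(n_rows, seed) {
  if (n_rows < 5) abort("`n_rows` must be at least 5 for a 4:1 split.")
  n_test <- round(n_rows / 5)
  perm <- with_seed(seed, sample.int(n_rows))
  structure(list(train = sort(perm[-seq_len(n_test)]),
                 test = sort(perm[seq_len(n_test)]),
                 seed = as.integer(seed)),
            class = "split_indices")
}

#' @export
print.split_indices <- function(x, ...) {
  cat("<split_indices>", length(x$train), "train /", length(x$test),
      "test (seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}

is_binary_col <- function(x) all(stats::na.omit(x) %in% c(0, 1))

#' Fit train-derived imputation and scaling
#'
#' Computes, from the training partition only: the mean of each continuous
#' feature and the mode of each binary feature (the imputation values), then
#' the mean and standard deviation of each column of the imputed training
#' matrix (the scaling parameters).  Applying the state to the training
#' table therefore yields columns with mean 0 and sd 1 exactly.
#'
#' @param train_features Data frame of numeric feature columns (the training
#'   partition), possibly with missing entries.
#' @return An object of class `preprocess_state`.
#' @export
fit_preprocess <- function(train_features) {
  stopifnot(is.data.frame(train_features) || is.matrix(train_features))
  df <- as.data.frame(train_features)
  feats <- names(df)
  binary <- vapply(df, is_binary_col, logical(1))
  impute <- vapply(feats, function(f) {
    x <- df[[f]]
    if (all(is.na(x))) abort(sprintf("Column `%s` is entirely missing.", f))
    if (binary[f]) {
      tb <- table(factor(stats::na.omit(x), levels = c(0, 1)))
      # mode; a 50/50 tie resolves to 0 for determinism
      as.numeric(names(tb)[which.max(tb)])
    } else {
      mean(x, na.rm = TRUE)
    }
  }, numeric(1))
  imputed <- as.matrix(df)
  for (f in feats) imputed[is.na(imputed[, f]), f] <- impute[f]
  center <- colMeans(imputed)
  # population standard deviation: the imputed training columns map exactly
  # to zero mean, unit variance
  scale_ <- sqrt(colMeans(sweep(imputed, 2, center, "-")^2))
  if (any(scale_ <= 0 | !is.finite(scale_))) {
    bad <- feats[scale_ <= 0 | !is.finite(scale_)]
    abort(paste0("Zero-variance training column(s): ",
                 paste(bad, collapse = ", "),
                 ". Scaling to unit variance is undefined."))
  }
  structure(list(features = feats, binary = binary, impute = impute,
                 center = center, scale = scale_),
            class = "preprocess_state")
}

#' @export
print.preprocess_state <- function(x, ...) {
  cat("<preprocess_state>", length(x$features), "features;",
      sum(x$binary), "binary (mode-imputed),",
      sum(!x$binary), "continuous (mean-imputed)\n")
  invisible(x)
}

#' Apply a fitted preprocessing state
#'
#' Imputes missing entries with the stored train means/modes and then
#' standardizes every column by the stored train center and scale.
#'
#' @param state A [fit_preprocess()] result.
#' @param features Data frame with the same columns the state was fit on.
#' @return A numeric matrix.
#' @export
apply_preprocess <- function(state, features) {
  stopifnot(inherits(state, "preprocess_state"))
  df <- as.data.frame(features)
  if (!identical(sort(names(df)), sort(state$features))) {
    abort("`features` columns do not match the fitted preprocessing state.")
  }
  X <- as.matrix(df[state$features])
  for (f in state$features) X[is.na(X[, f]), f] <- state$impute[f]
  X <- sweep(X, 2, state$center, "-")
  sweep(X, 2, state$scale, "/")
}

#' Serialize / restore a preprocessing state as YAML
#' @param state A `preprocess_state`.
#' @param path File path.
#' @return `path` invisibly; `preprocess_state_from_yaml` returns the state.
#' @export
preprocess_state_to_yaml <- function(state, path) {
  yaml::write_yaml(list(features = state$features,
                        binary = as.list(state$binary),
                        impute = as.list(state$impute),
                        center = as.list(state$center),
                        scale = as.list(state$scale)), path)
  invisible(path)
}

#' @rdname preprocess_state_to_yaml
#' @export
preprocess_state_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  structure(list(features = unlist(x$features),
                 binary = unlist(x$binary), impute = unlist(x$impute),
                 center = unlist(x$center), scale = unlist(x$scale)),
            class = "preprocess_state")
}

#' Random undersampling to a uniform class distribution
#'
#' Keeps every minority-class row and a seeded random subset (without
#' replacement) of the majority class of equal size.
#'
#' @param labels Binary 0/1 vector.
#' @param seed Integer seed.
#' @return Sorted integer vector of retained row indices.
#' @export
subsample_balance <- function(labels, seed) {
  assert_binary(labels, "labels")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    abort("Both classes must be present to balance by subsampling.")
  }
  minority <- if (n1 <= n0) 1 else 0
  keep_min <- which(labels == minority)
  maj <- which(labels != minority)
  keep_maj <- with_seed(seed, maj[sample.int(length(maj), length(keep_min))])
  sort(c(keep_min, keep_maj))
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j), with R^2_j from the least-squares regression of
#' feature j on all other features (with intercept).  Exactly collinear
#' features are reported as infinite and flagged.
#'
#' @param features Numeric matrix or data frame; >= 2 columns, more rows
#'   than columns, no missing values.
#' @return A tibble with columns `feature`, `vif`, `aliased`.
#' @export
compute_vif <- function(features) {
  X <- as_feature_matrix(features)
  if (anyNA(X)) abort("`features` must not contain missing values.")
  p <- ncol(X)
  if (p < 2) abort("VIF needs at least 2 features.")
  if (nrow(X) <= p) abort("VIF needs more rows than features.")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  vifs <- vapply(seq_len(p), function(j) {
    yj <- X[, j]
    Z <- cbind(1, X[, -j, drop = FALSE])
    fit <- stats::lm.fit(Z, yj)
    rss <- sum(fit$residuals^2)
    tss <- sum((yj - mean(yj))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  tibble::tibble(feature = colnames(X), vif = vifs,
                 aliased = !is.finite(vifs))
}
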