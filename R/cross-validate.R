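# Exhaustive grid search with seeded k-fold cross-validation, selecting the
# configuration with the highest mean validation AUC; ties break toward the
# stronger regularization, then grid order.

#' Default hyperparameter grids
#'
#' The full tuning grids for the four tuned model families (the GLM is fit
#' unregularized and has no grid): Lasso inverse strength `C`; elastic-net
#' `l1_ratio` and `alpha`; GBDT tree depth, learning rate, bagging
#' temperature, L2 leaf regularization and leaf-estimation iterations; MLP
#' hidden units, learning rate, batch size, dropout rate and L1 ratio.
#'
#' @return A named list of class `hyper_grid`: per family, a named list of
#'   candidate value vectors.
#' @export
default_hyper_grid <- function() {
  structure(list(
    lasso = list(
      C = c(0.10, 0.12, 0.15, 0.18, 0.21, 0.26, 0.31, 0.37, 0.45, 0.54,
            0.66, 0.79, 0.95, 1.15, 1.39, 1.68, 2.02, 2.44, 2.95, 3.56,
            4.29, 5.18, 6.25, 7.54, 9.10, 10.9, 13.3, 16.0, 19.3, 23.3,
            28.1, 33.9, 40.9, 49.4, 59.6, 72.0, 86.9, 105, 126, 153,
            184, 222, 268, 324, 391, 471, 569, 687, 829, 1000)),
    elastic_net = list(
      l1_ratio = seq(0, 0.95, by = 0.05),
      alpha = c(0.00001, 0.00004, 0.00016, 0.0006, 0.0025, 0.01, 0.04,
                0.16, 0.63, 2.5, 10)),
    gbdt = list(
      depth = c(2, 4),
      learning_rate = c(0.03, 0.1, 0.3),
      bagging_temperature = c(0.6, 0.8, 1),
      l2_leaf_reg = c(3, 10, 100, 500),
      leaf_estimation_iterations = c(1, 2)),
    mlp = list(
      hidden_units = c(5, 10, 15, 20),
      learning_rate = c(0.001, 0.01),
      batch_size = c(16, 32),
      dropout_rate = c(0.1, 0.2),
      l1_ratio = c(0.0001, 0.001))),
    class = "hyper_grid")
}

#' Read / write a hyperparameter grid as YAML
#' @param path YAML file path.
#' @param grid A `hyper_grid`.
#' @return `hyper_grid_from_yaml` returns a `hyper_grid`; the writer
#'   returns `path` invisibly.
#' @export
hyper_grid_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  structure(lapply(x, function(fam) lapply(fam, unlist)),
            class = "hyper_grid")
}

#' @rdname hyper_grid_from_yaml
#' @export
hyper_grid_to_yaml <- function(grid, path) {
  yaml::write_yaml(lapply(unclass(grid), function(fam)
    lapply(fam, as.vector)), path)
  invisible(path)
}

expand_grid_family <- function(grid_family) {
  g <- do.call(expand.grid,
               c(grid_family, list(KEEP.OUT.ATTRS = FALSE,
                                   stringsAsFactors = FALSE)))
  unique(tibble::as_tibble(g))
}

# lower = stronger regularization (tie-break preference)
regularization_rank <- function(family, configs) {
  switch(family,
    lasso = rank(configs$C, ties.method = "first"),
    elastic_net = rank(-configs$alpha * 1e6 - configs$l1_ratio,
                       ties.method = "first"),
    gbdt = rank(-configs$l2_leaf_reg * 1e3 + configs$depth,
                ties.method = "first"),
    mlp = rank(-configs$l1_ratio * 1e6 - configs$dropout_rate * 1e3 +
                 configs$hidden_units, ties.method = "first"),
    seq_len(nrow(configs)))
}

#' Fit one model family at a given configuration
#'
#' @param family One of `"glm"`, `"lasso"`, `"elastic_net"`, `"gbdt"`,
#'   `"mlp"`.
#' @param X,y Training data (complete, standardized features; 0/1 labels).
#' @param config Named list/row of hyperparameter values (ignored for
#'   `"glm"`); omitted parameters take their family defaults.
#' @param seed Seed for the stochastic learners.
#' @return A fitted model object.
#' @export
fit_family <- function(family, X, y, config = list(), seed = 1L) {
  config <- as.list(config)
  switch(family,
    glm = fit_glm(X, y),
    lasso = fit_lasso(X, y, C = config$C),
    elastic_net = fit_elastic_net(X, y, alpha = config$alpha,
                                  l1_ratio = config$l1_ratio),
    gbdt = fit_gbdt(X, y,
                    hyper = do.call(gbdt_hyper,
                                    config[intersect(names(config),
                                                     names(formals(gbdt_hyper)))]),
                    seed = seed),
    mlp = fit_mlp(X, y,
                  hyper = do.call(mlp_hyper,
                                  config[intersect(names(config),
                                                   names(formals(mlp_hyper)))]),
                  seed = seed),
    abort(sprintf("Unknown model family `%s`.", family)))
}

#' Tune a model family by k-fold cross-validation
#'
#' Exhaustive search over the family's grid.  Folds are a seeded partition
#' of the (balanced) training rows; the selection metric is the mean
#' validation AUC.  Ties break toward the stronger regularization, then
#' grid order.  Folds containing a single class are skipped with a warning;
#' if every fold is degenerate the search aborts.  A single-configuration
#' grid is returned directly without fitting.
#'
#' @inheritParams fit_family
#' @param grid Named list of candidate value vectors for the family (e.g.
#'   one element of [default_hyper_grid()]), or a data frame of explicit
#'   configurations.
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold partition and the stochastic learners.
#' @return A list with `best` (named list of chosen values), `mean_auc`
#'   (of the chosen configuration; `NA` for a size-1 grid shortcut) and
#'   `results` (per-configuration tibble).
#' @export
cross_validate <- function(family, X, y, grid, k = 10, seed = 1L) {
  X <- as_feature_matrix(X)
  configs <- if (is.data.frame(grid)) unique(tibble::as_tibble(grid))
             else expand_grid_family(grid)
  if (family == "glm" || nrow(configs) == 0) {
    return(list(best = list(), mean_auc = NA_real_,
                results = tibble::tibble()))
  }
  if (nrow(configs) == 1) {
    return(list(best = as.list(configs[1, ]), mean_auc = NA_real_,
                results = dplyr::mutate(configs, mean_auc = NA_real_)))
  }
  n <- nrow(X)
  if (n < k) abort("Fewer rows than folds.")
  fold <- with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  mean_aucs <- vapply(seq_len(nrow(configs)), function(ci) {
    cfg <- as.list(configs[ci, ])
    aucs <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      if (length(unique(y[!tr])) < 2 || length(unique(y[tr])) < 2) {
        return(NA_real_)
      }
      fit <- fit_family(family, X[tr, , drop = FALSE], y[tr], cfg,
                        seed = derive_seed(seed, ci, stream = f))
      roc_auc(predict_proba(fit, X[!tr, , drop = FALSE]), y[!tr])
    }, numeric(1))
    if (anyNA(aucs)) {
      warn(sprintf("%d degenerate single-class fold(s) skipped.",
                   sum(is.na(aucs))))
    }
    if (all(is.na(aucs))) {
      abort("All cross-validation folds were degenerate.")
    }
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  rr <- regularization_rank(family, configs)
  best_i <- order(-mean_aucs, rr, seq_len(nrow(configs)))[1]
  list(best = as.list(configs[best_i, ]),
       mean_auc = mean_aucs[best_i],
       results = dplyr::mutate(configs, mean_auc = mean_aucs))
}
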