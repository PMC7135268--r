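# End-to-end experiment driver: repeated shuffles of
# split -> impute/scale -> balance -> 10-fold CV tuning -> fit -> test AUC
# -> model-tailored interpretability, for all five model families, with
# counter-based per-shuffle seeds and reproducible CSV artifacts.

ALL_FAMILIES <- c("glm", "lasso", "elastic_net", "gbdt", "mlp")

#' Configure an experiment
#'
#' @param cohort The cohort to analyze: a [cohort_spec()] (generated at run
#'   time), a data frame with the seven features plus `mrs`, or a CSV path.
#' @param n_shuffles Number of repetitions of the whole protocol
#'   (default 50).
#' @param cv_folds Cross-validation folds for tuning (default 10).
#' @param grid A `hyper_grid` (default [default_hyper_grid()]).
#' @param models Model families to run (default all five).
#' @param compute_importance Whether to compute feature-importance ratings
#'   (default `TRUE`).
#' @param importance_on Partition whose observations are explained:
#'   `"test"` (default) or `"train"` (the balanced training set).
#' @param shap_background Number of training rows in the Shapley background
#'   sample (default 100).
#' @param shap_max_obs Cap on the number of observations explained by exact
#'   Shapley enumeration per shuffle (default 200).
#' @param shap_abs_per_obs Take absolute Shapley values per observation
#'   before averaging (default `FALSE`: signed means, absolute values at
#'   normalization).
#' @param lrp_class_neuron Output neuron seeding the deep-Taylor relevance:
#'   `"bad"` (default) or `"predicted"`; see [lrp_deep_taylor()].
#' @param lrp_abs_per_obs Take absolute relevances per observation before
#'   the confidence-weighted average (default `TRUE`; relevance is
#'   non-negative in the rule's native non-negative-activation domain, and
#'   signed averaging cancels for symmetric continuous covariates).
#' @param seed Master seed; per-shuffle seeds are derived from it.
#' @param output_dir Optional directory for CSV artifacts
#'   (`performance.csv`, `importance.csv`, `vif.csv`,
#'   `shuffles/shuffle_<k>.csv`).
#' @param write_figures Also save ggplot figures under
#'   `<output_dir>/figures` (default `FALSE`).
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_spec(), n_shuffles = 50,
                              cv_folds = 10, grid = default_hyper_grid(),
                              models = ALL_FAMILIES,
                              compute_importance = TRUE,
                              importance_on = c("test", "train"),
                              shap_background = 100, shap_max_obs = 200,
                              shap_abs_per_obs = FALSE,
                              lrp_class_neuron = c("bad", "predicted"),
                              lrp_abs_per_obs = TRUE,
                              seed = 1L, output_dir = NULL,
                              write_figures = FALSE) {
  if (n_shuffles < 1) abort("`n_shuffles` must be at least 1.")
  if (cv_folds < 2) abort("`cv_folds` must be at least 2.")
  bad <- setdiff(models, ALL_FAMILIES)
  if (length(bad)) {
    abort(paste("Unknown model families:", paste(bad, collapse = ", ")))
  }
  structure(list(cohort = cohort, n_shuffles = as.integer(n_shuffles),
                 cv_folds = as.integer(cv_folds), grid = grid,
                 models = models, compute_importance = compute_importance,
                 importance_on = match.arg(importance_on),
                 shap_background = shap_background,
                 shap_max_obs = shap_max_obs,
                 shap_abs_per_obs = shap_abs_per_obs,
                 lrp_class_neuron = match.arg(lrp_class_neuron),
                 lrp_abs_per_obs = lrp_abs_per_obs,
                 seed = as.integer(seed),
                 output_dir = output_dir, write_figures = write_figures),
            class = "experiment_config")
}

resolve_cohort <- function(cohort) {
  if (inherits(cohort, "cohort_spec")) return(generate_cohort(cohort))
  if (is.character(cohort)) return(read_cohort(cohort))
  if (is.data.frame(cohort)) return(cohort)
  abort("`cohort` must be a cohort_spec, a data frame or a CSV path.")
}

# one shuffle of the full protocol; returns per-model AUCs + raw importances
run_shuffle <- function(cohort, labels, config, shuffle_seed) {
  feats <- cohort_features()
  features <- cohort[feats]
  split <- split_train_test(nrow(cohort), seed = derive_seed(shuffle_seed, 1L))
  state <- fit_preprocess(features[split$train, ])
  Xtr <- apply_preprocess(state, features[split$train, ])
  Xte <- apply_preprocess(state, features[split$test, ])
  ytr <- labels[split$train]
  yte <- labels[split$test]
  bal <- subsample_balance(ytr, seed = derive_seed(shuffle_seed, 2L))
  Xb <- Xtr[bal, , drop = FALSE]
  yb <- ytr[bal]
  if (config$importance_on == "test") {
    X_expl <- Xte; y_expl <- yte
  } else {
    X_expl <- Xb; y_expl <- yb
  }
  rows <- list(); importances <- list()
  for (mi in seq_along(config$models)) {
    family <- config$models[mi]
    cv <- cross_validate(family, Xb, yb,
                         grid = config$grid[[family]] %||% list(),
                         k = config$cv_folds,
                         seed = derive_seed(shuffle_seed, 10L + mi))
    fit <- fit_family(family, Xb, yb, cv$best,
                      seed = derive_seed(shuffle_seed, 40L + mi))
    rows[[family]] <- tibble::tibble(
      model = family,
      partition = c("train", "test"),
      auc = c(roc_auc(predict_proba(fit, Xb), yb),
              roc_auc(predict_proba(fit, Xte), yte)),
      hyper = yaml::as.yaml(cv$best))
    if (config$compute_importance) {
      importances[[family]] <- model_importance(
        family, fit, Xb, X_expl, y_expl, config, shuffle_seed, mi)
    }
  }
  list(performance = dplyr::bind_rows(rows), importances = importances)
}

model_importance <- function(family, fit, Xb, X_expl, y_expl, config,
                             shuffle_seed, mi) {
  if (family %in% c("glm", "lasso", "elastic_net")) {
    return(linear_importance(fit))
  }
  if (family == "gbdt") {
    nbg <- min(config$shap_background, nrow(Xb))
    bg <- Xb[with_seed(derive_seed(shuffle_seed, 70L + mi),
                       sample.int(nrow(Xb), nbg)), , drop = FALSE]
    nobs <- min(config$shap_max_obs, nrow(X_expl))
    obs_idx <- with_seed(derive_seed(shuffle_seed, 80L + mi),
                         sort(sample.int(nrow(X_expl), nobs)))
    phis <- shapley_matrix(function(m) predict_proba(fit, m),
                           X_expl[obs_idx, , drop = FALSE], bg)
    if (isTRUE(config$shap_abs_per_obs)) phis <- abs(phis)
    return(aggregate_shap(phis))
  }
  # mlp: deep Taylor relevances, confidence-weighted over observations
  rel <- lrp_matrix(fit, X_expl, class_neuron = config$lrp_class_neuron)
  if (isTRUE(config$lrp_abs_per_obs)) rel <- abs(rel)
  confidence_weighted_rating(rel, predict_proba(fit, X_expl), y_expl)
}

#' Run the full repeated-shuffle experiment
#'
#' Executes, for each shuffle: random 4:1 split, train-derived mean/mode
#' imputation and zero-mean unit-variance scaling, random undersampling of
#' the majority class, per-family 10-fold cross-validated tuning, final
#' fits, train/test AUC, and the model-tailored importance methods.
#' Summaries are the per-model median AUC with IQR and the per-feature
#' mean and standard deviation of the unit-sum normalized ratings.  A
#' failed shuffle is logged and excluded; more than 20% failures aborts.
#' Rerunning with the same configuration reproduces identical artifacts.
#'
#' @param config An [experiment_config()].
#' @return A list of class `experiment_report`: `performance`,
#'   `importance`, `vif`, `shuffles`, `failed`, `config`, `seeds`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  cohort <- resolve_cohort(config$cohort)
  labels <- dichotomize_mrs(cohort$mrs)
  feats <- cohort_features()
  cc <- complete.cases(cohort[feats])
  vif <- compute_vif(cohort[cc, feats])
  seeds <- vapply(seq_len(config$n_shuffles),
                  function(k) derive_seed(config$seed, k), integer(1))
  shuffles <- vector("list", config$n_shuffles)
  failed <- character(0)
  for (k in seq_len(config$n_shuffles)) {
    shuffles[[k]] <- tryCatch(
      run_shuffle(cohort, labels, config, seeds[k]),
      error = function(e) {
        failed <<- c(failed, sprintf("shuffle %d: %s", k, conditionMessage(e)))
        NULL
      })
  }
  ok <- !vapply(shuffles, is.null, logical(1))
  if (mean(!ok) > 0.2) {
    abort(paste0("More than 20% of shuffles failed:\n",
                 paste(failed, collapse = "\n")))
  }
  perf <- dplyr::bind_rows(lapply(which(ok), function(k) {
    dplyr::mutate(shuffles[[k]]$performance, shuffle = k, .before = 1)
  }))
  performance <- summarize_performance(perf)
  importance <- NULL
  if (config$compute_importance) {
    importance <- dplyr::bind_rows(lapply(config$models, function(fam) {
      raws <- lapply(which(ok), function(k) shuffles[[k]]$importances[[fam]])
      summ <- normalize_importance(raws)
      method <- attr(raws[[1]], "method")
      dplyr::mutate(summ, model = fam, method = method, .before = 1)
    }))
  }
  report <- structure(
    list(performance = performance, importance = importance, vif = vif,
         shuffles = perf, failed = failed, config = config, seeds = seeds),
    class = "experiment_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$performance, file.path(dir, "performance.csv"))
  if (!is.null(report$importance)) {
    readr::write_csv(report$importance, file.path(dir, "importance.csv"))
  }
  readr::write_csv(report$vif, file.path(dir, "vif.csv"))
  shdir <- file.path(dir, "shuffles")
  dir.create(shdir, showWarnings = FALSE)
  for (k in unique(report$shuffles$shuffle)) {
    readr::write_csv(report$shuffles[report$shuffles$shuffle == k, ],
                     file.path(shdir, sprintf("shuffle_%d.csv", k)))
  }
  if (isTRUE(report$config$write_figures)) {
    figdir <- file.path(dir, "figures")
    dir.create(figdir, showWarnings = FALSE)
    tryCatch({
      ggplot2::ggsave(file.path(figdir, "performance.png"),
                      plot_performance(report), width = 7, height = 4.5,
                      dpi = 150)
      if (!is.null(report$importance)) {
        ggplot2::ggsave(file.path(figdir, "importance.png"),
                        plot_importance(report), width = 8, height = 5,
                        dpi = 150)
      }
    }, error = function(e) warn(paste("Figure export failed:",
                                      conditionMessage(e))))
  }
  invisible(dir)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>", length(x$seeds), "shuffles;",
      length(x$failed), "failed\n\nPerformance (median AUC / IQR):\n")
  print(x$performance, n = Inf)
  if (!is.null(x$importance)) {
    cat("\nTop-rated features per model:\n")
    top <- dplyr::slice_max(dplyr::group_by(x$importance, .data$model),
                            .data$mean_rating, n = 2)
    print(dplyr::ungroup(top), n = Inf)
  }
  invisible(x)
}

#' @export
tidy.experiment_report <- function(x, ...) x$performance

#' @export
glance.experiment_report <- function(x, ...) {
  test <- x$performance[x$performance$partition == "test", ]
  tibble::tibble(n_shuffles = length(x$seeds),
                 n_failed = length(x$failed),
                 n_models = length(unique(test$model)),
                 median_test_auc = median(test$median_auc),
                 max_vif = max(x$vif$vif))
}
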