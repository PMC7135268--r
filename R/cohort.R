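# Synthetic clinical cohorts: a latent Gaussian copula over seven covariates
# (age, sex, initial NIHSS, cardiac history, diabetes, hypercholesterolemia,
# thrombolysis) plus a planted logistic ground truth for the dichotomized
# modified Rankin Scale (mRS) outcome.

# NIHSS marginal: gamma calibrated so the ROUNDED variable has median 3 and
# IQR 5 at large n (gamma is already non-negative, so no shift is needed).
NIHSS_SHAPE <- 0.9285023
NIHSS_SCALE <- 4.806674

# age IQR -> sd for a normal marginal: IQR = 2 * qnorm(0.75) * sd
iqr_to_sd <- function(iqr) iqr / (2 * qnorm(0.75))

# exact moments of round(gamma(shape, scale)) by summing over the support
rounded_gamma_moments <- function(shape, scale, upper = 400L) {
  j <- 0:upper
  p <- pgamma(j + 0.5, shape = shape, scale = scale) -
    pgamma(pmax(j - 0.5, 0), shape = shape, scale = scale)
  p[length(p)] <- p[length(p)] + pgamma(upper + 0.5, shape, scale = scale,
                                        lower.tail = FALSE)
  mu <- sum(j * p)
  list(mean = mu, sd = sqrt(sum((j - mu)^2 * p)))
}

#' Specify a synthetic stroke cohort
#'
#' Builds the full description of a synthetic cohort: marginal distributions
#' matched to the study population (median age 72, IQR 15; median initial
#' NIHSS 3, IQR 5; binary prevalences for sex, cardiac history, diabetes,
#' hypercholesterolemia and thrombolysis), a weak exchangeable latent
#' correlation, a planted logistic ground truth on standardized features in
#' which the age and NIHSS coefficients dominate, completely-at-random
#' missingness, and a seed.  The intercept of the planted model is calibrated
#' numerically (fixed internal Monte-Carlo sample) so that the expected
#' bad-outcome prevalence matches `target_prevalence`.
#'
#' @param n_subjects Number of subjects (default 314, the study size).
#' @param age_center,age_iqr Location and interquartile range of the normal
#'   age marginal (years).
#' @param nihss_shape,nihss_scale Gamma parameters of the (rounded) NIHSS
#'   marginal; defaults are calibrated to median 3 / IQR 5.
#' @param prevalences Named probabilities for the five binary features, in
#'   `(0, 1)`.  Defaults are the study prevalences (e.g. 118/314 male).
#' @param latent_correlation Either a single exchangeable latent correlation
#'   (default 0.15, weak enough to keep all VIFs well below 1.91) or a full
#'   symmetric positive-definite 7x7 matrix with unit diagonal.
#' @param planted_coefficients Named log-odds coefficients per standardized
#'   feature.  Defaults: age and NIHSS at +1, the treatment (thrombolysis)
#'   at -0.25, all other covariates at +0.25.
#' @param intercept Planted intercept; `NULL` (default) calibrates it to
#'   `target_prevalence`.
#' @param target_prevalence Expected bad-outcome fraction used when
#'   calibrating the intercept (default 88/314).
#' @param missing_rate MCAR missingness fraction in `[0, 0.05]`.
#' @param seed Integer seed; the generated cohort is a pure function of the
#'   spec including this seed.
#' @return An object of class `cohort_spec`.
#' @export
#' @examples
#' spec <- cohort_spec(n_subjects = 100, seed = 1)
#' cohort <- generate_cohort(spec)
cohort_spec <- function(n_subjects = 314,
                        age_center = 72, age_iqr = 15,
                        nihss_shape = NIHSS_SHAPE, nihss_scale = NIHSS_SCALE,
                        prevalences = c(sex = 118 / 314, cardiac = 84 / 314,
                                        diabetes = 79 / 314,
                                        hypercholesterolemia = 182 / 314,
                                        thrombolysis = 74 / 314),
                        latent_correlation = 0.15,
                        planted_coefficients = c(age = 1, sex = 0.25,
                                                 nihss = 1, cardiac = 0.25,
                                                 diabetes = 0.25,
                                                 hypercholesterolemia = 0.25,
                                                 thrombolysis = -0.25),
                        intercept = NULL,
                        target_prevalence = 88 / 314,
                        missing_rate = 0.02,
                        seed = 1L) {
  feats <- cohort_features()
  bin <- setdiff(feats, c("age", "nihss"))
  if (n_subjects < 0 || n_subjects != round(n_subjects)) {
    abort("`n_subjects` must be a non-negative integer.")
  }
  if (!all(bin %in% names(prevalences))) {
    abort(paste("`prevalences` must name all of:", paste(bin, collapse = ", ")))
  }
  prevalences <- prevalences[bin]
  if (any(prevalences <= 0 | prevalences >= 1)) {
    abort("All prevalences must lie strictly inside (0, 1).")
  }
  if (missing_rate < 0 || missing_rate > 0.05) {
    abort("`missing_rate` must lie in [0, 0.05] (at most 5% missing values).")
  }
  R <- latent_correlation
  if (length(R) == 1) {
    R <- matrix(R, 7, 7)
    diag(R) <- 1
  }
  if (!isTRUE(all.equal(diag(R), rep(1, 7))) || !isSymmetric(unname(R))) {
    abort("`latent_correlation` must be symmetric with unit diagonal.")
  }
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) {
    abort("`latent_correlation` is not positive definite (Cholesky failed).")
  }
  if (!all(feats %in% names(planted_coefficients))) {
    abort("`planted_coefficients` must name all seven features.")
  }
  planted_coefficients <- planted_coefficients[feats]

  nm <- rounded_gamma_moments(nihss_shape, nihss_scale)
  moments <- list(
    mean = c(age = age_center, sex = unname(prevalences["sex"]),
             nihss = nm$mean,
             cardiac = unname(prevalences["cardiac"]),
             diabetes = unname(prevalences["diabetes"]),
             hypercholesterolemia = unname(prevalences["hypercholesterolemia"]),
             thrombolysis = unname(prevalences["thrombolysis"])),
    sd = c(age = iqr_to_sd(age_iqr), sex = NA, nihss = nm$sd,
           cardiac = NA, diabetes = NA, hypercholesterolemia = NA,
           thrombolysis = NA)
  )
  moments$sd[bin] <- sqrt(prevalences * (1 - prevalences))[bin]

  spec <- structure(
    list(n_subjects = as.integer(n_subjects),
         age_center = age_center, age_iqr = age_iqr,
         nihss_shape = nihss_shape, nihss_scale = nihss_scale,
         prevalences = prevalences,
         latent_correlation = R, chol_R = ch,
         planted_coefficients = planted_coefficients,
         intercept = intercept, target_prevalence = target_prevalence,
         missing_rate = missing_rate, moments = moments,
         seed = as.integer(seed)),
    class = "cohort_spec")
  if (is.null(spec$intercept)) {
    spec$intercept <- calibrate_intercept(spec)
  }
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> n =", x$n_subjects,
      "| prevalence target =", signif(x$target_prevalence, 4),
      "| intercept =", signif(x$intercept, 4),
      "| missing rate =", x$missing_rate, "\n")
  invisible(x)
}

# draw the complete (pre-missingness) feature table from the latent copula
draw_features <- function(spec, n) {
  feats <- cohort_features()
  if (n == 0) {
    X <- matrix(numeric(0), 0, 7, dimnames = list(NULL, feats))
    return(as.data.frame(X))
  }
  Z <- matrix(rnorm(n * 7), n, 7) %*% spec$chol_R
  U <- pnorm(Z)
  colnames(U) <- feats
  out <- data.frame(
    age = qnorm(U[, "age"], mean = spec$age_center,
                sd = iqr_to_sd(spec$age_iqr)),
    sex = as.numeric(U[, "sex"] < spec$prevalences["sex"]),
    nihss = round(qgamma(U[, "nihss"], shape = spec$nihss_shape,
                         scale = spec$nihss_scale)),
    cardiac = as.numeric(U[, "cardiac"] < spec$prevalences["cardiac"]),
    diabetes = as.numeric(U[, "diabetes"] < spec$prevalences["diabetes"]),
    hypercholesterolemia =
      as.numeric(U[, "hypercholesterolemia"] <
                   spec$prevalences["hypercholesterolemia"]),
    thrombolysis = as.numeric(U[, "thrombolysis"] <
                                spec$prevalences["thrombolysis"])
  )
  out
}

# population-standardized features -> planted linear predictor
planted_linear_predictor <- function(spec, features) {
  feats <- cohort_features()
  Xs <- sweep(as.matrix(features[feats]), 2, spec$moments$mean[feats], "-")
  Xs <- sweep(Xs, 2, spec$moments$sd[feats], "/")
  drop(spec$intercept + Xs %*% spec$planted_coefficients[feats])
}

# intercept such that mean over a fixed latent MC sample of sigmoid(b0 + s)
# hits the target prevalence
calibrate_intercept <- function(spec, n_cal = 20000L) {
  X <- with_seed(20200406L, draw_features(spec, n_cal))
  s <- local({
    sp <- spec
    sp$intercept <- 0
    planted_linear_predictor(sp, X)
  })
  if (all(spec$planted_coefficients == 0)) {
    return(qlogis(spec$target_prevalence))
  }
  uniroot(function(b0) mean(plogis(b0 + s)) - spec$target_prevalence,
          interval = c(-20, 20), extendInt = "upX", tol = 1e-10)$root
}

#' Generate a synthetic cohort
#'
#' Draws features from the spec's latent-Gaussian copula, computes the
#' planted bad-outcome probability through the logistic link, samples the
#' binary outcome, then draws an mRS value uniformly within the matching
#' half (0-2 good, 3-6 bad) so that dichotomization reproduces the planted
#' probability exactly.  MCAR missingness is applied to the features last.
#' The result is bit-identical across runs with the same spec.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with the seven feature columns and `mrs`, carrying the
#'   planted truth (`attr(, "truth")`) and the spec (`attr(, "spec")`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  cohort <- with_seed(spec$seed, {
    X <- draw_features(spec, n)
    if (n > 0) {
      p_bad <- plogis(planted_linear_predictor(spec, X))
      bad <- runif(n) < p_bad
      mrs <- ifelse(bad, 3L + sample.int(4, n, replace = TRUE) - 1L,
                    sample.int(3, n, replace = TRUE) - 1L)
      if (spec$missing_rate > 0) {
        mask <- matrix(runif(n * 7) < spec$missing_rate, n, 7)
        Xm <- as.matrix(X)
        Xm[mask] <- NA_real_
        X <- as.data.frame(Xm)
      }
    } else {
      mrs <- integer(0)
    }
    out <- tibble::as_tibble(X)
    out$mrs <- as.integer(mrs)
    out
  })
  attr(cohort, "truth") <- list(
    coefficients = spec$planted_coefficients,
    intercept = spec$intercept,
    moments = spec$moments)
  attr(cohort, "spec") <- spec
  cohort
}

#' Check a cohort's empirical marginals against its spec
#'
#' Report-only diagnostic: compares empirical medians (age, NIHSS) and
#' prevalences (binary features) with the spec's targets.
#'
#' @param cohort A generated cohort.
#' @param spec The [cohort_spec()] it came from.
#' @param median_tol Allowed absolute deviation of medians (default 1 unit).
#' @param prevalence_tol Allowed absolute deviation of prevalences
#'   (default 0.03; intended for n >= 10,000).
#' @return A tibble with one row per checked marginal: `feature`,
#'   `statistic`, `target`, `observed`, `tolerance`, `pass`, and a `status`
#'   attribute (`"ok"` or `"insufficient data"`).
#' @export
validate_marginals <- function(cohort, spec, median_tol = 1,
                               prevalence_tol = 0.03) {
  bin <- names(spec$prevalences)
  targets <- tibble::tibble(
    feature = c("age", "nihss", bin),
    statistic = c("median", "median", rep("prevalence", length(bin))),
    target = c(spec$age_center, 3, unname(spec$prevalences)),
    tolerance = c(median_tol, median_tol, rep(prevalence_tol, length(bin)))
  )
  if (nrow(cohort) == 0) {
    out <- dplyr::mutate(targets, observed = NA_real_, pass = NA)
    attr(out, "status") <- "insufficient data"
    return(out)
  }
  obs <- vapply(seq_len(nrow(targets)), function(i) {
    x <- cohort[[targets$feature[i]]]
    if (targets$statistic[i] == "median") median(x, na.rm = TRUE)
    else mean(x, na.rm = TRUE)
  }, numeric(1))
  out <- dplyr::mutate(targets, observed = obs,
                       pass = abs(obs - .data$target) <= .data$tolerance)
  attr(out, "status") <- "ok"
  out
}

#' Monte-Carlo AUC of the planted ground truth
#'
#' Estimates the AUC the true linear predictor achieves on fresh data drawn
#' from the spec: the performance ceiling any fitted model can approach.
#'
#' @param spec A [cohort_spec()].
#' @param n_mc Monte-Carlo sample size (>= 1000).
#' @param seed Seed for the fresh draw (defaults to a stream derived from
#'   the spec's seed).
#' @return A single AUC value.
#' @export
planted_truth_auc <- function(spec, n_mc = 100000L, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (n_mc < 1000) abort("`n_mc` must be at least 1000.")
  seed <- seed %||% derive_seed(spec$seed, 0L, stream = 77L)
  with_seed(seed, {
    X <- draw_features(spec, n_mc)
    lp <- planted_linear_predictor(spec, X)
    y <- as.numeric(runif(n_mc) < plogis(lp))
    roc_auc(lp, y)
  })
}

#' Write / read a cohort as CSV (with a YAML sidecar for the spec)
#'
#' The CSV has the canonical header
#' `age,sex,nihss,cardiac,diabetes,hypercholesterolemia,thrombolysis,mrs`;
#' missing entries are empty fields.  When the cohort carries its spec, a
#' `<path>.spec.yaml` sidecar is written alongside.
#'
#' @param cohort A cohort tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cols <- c(cohort_features(), "mrs")
  stopifnot(all(cols %in% names(cohort)))
  readr::write_csv(cohort[cols], path, na = "")
  spec <- attr(cohort, "spec")
  if (!is.null(spec)) {
    yaml::write_yaml(spec_to_list(spec), paste0(path, ".spec.yaml"),
                     precision = 15)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- readr::read_csv(path, col_types = readr::cols(
    mrs = readr::col_integer(), .default = readr::col_double()))
  side <- paste0(path, ".spec.yaml")
  if (file.exists(side)) {
    attr(cohort, "spec") <- spec_from_list(yaml::read_yaml(side))
  }
  cohort
}

spec_to_list <- function(spec) {
  list(n_subjects = spec$n_subjects, age_center = spec$age_center,
       age_iqr = spec$age_iqr, nihss_shape = spec$nihss_shape,
       nihss_scale = spec$nihss_scale,
       prevalences = as.list(spec$prevalences),
       latent_correlation = as.vector(spec$latent_correlation),
       planted_coefficients = as.list(spec$planted_coefficients),
       intercept = spec$intercept,
       target_prevalence = spec$target_prevalence,
       missing_rate = spec$missing_rate, seed = spec$seed)
}

spec_from_list <- function(x) {
  cohort_spec(
    n_subjects = x$n_subjects, age_center = x$age_center,
    age_iqr = x$age_iqr, nihss_shape = x$nihss_shape,
    nihss_scale = x$nihss_scale, prevalences = unlist(x$prevalences),
    latent_correlation = matrix(unlist(x$latent_correlation), 7, 7),
    planted_coefficients = unlist(x$planted_coefficients),
    intercept = x$intercept, target_prevalence = x$target_prevalence,
    missing_rate = x$missing_rate, seed = x$seed)
}
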