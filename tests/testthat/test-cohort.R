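test_that("cohort generation is a pure function of the spec and seed", {
  spec <- cohort_spec(n_subjects = 200, seed = 42)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  other <- generate_cohort(cohort_spec(n_subjects = 200, seed = 43))
  expect_false(identical(a$age, other$age))
})

test_that("an empty spec yields an empty cohort without error", {
  ch <- generate_cohort(cohort_spec(n_subjects = 0, seed = 1))
  expect_equal(nrow(ch), 0)
  expect_named(ch, c(cohort_features(), "mrs"))
  rep <- validate_marginals(ch, cohort_spec(n_subjects = 0, seed = 1))
  expect_equal(attr(rep, "status"), "insufficient data")
})

test_that("invalid specs are rejected with diagnostics", {
  R_bad <- matrix(0.99, 7, 7); diag(R_bad) <- 1; R_bad[1, 2] <- -0.99
  R_bad[2, 1] <- -0.99  # symmetric but not positive definite with the rest
  expect_error(cohort_spec(latent_correlation = R_bad), "positive definite")
  expect_error(cohort_spec(missing_rate = 0.06), "missing_rate")
  expect_error(cohort_spec(prevalences = c(sex = 0, cardiac = 0.2,
                                           diabetes = 0.2,
                                           hypercholesterolemia = 0.5,
                                           thrombolysis = 0.2)),
               "prevalence")
})

test_that("large cohorts match the target marginals and the VIF budget", {
  spec <- cohort_spec(n_subjects = 20000, missing_rate = 0, seed = 7)
  ch <- generate_cohort(spec)
  rep <- validate_marginals(ch, spec)
  expect_true(all(rep$pass))
  # age and NIHSS IQRs near their targets (15 and 5)
  expect_lt(abs(diff(quantile(ch$age, c(0.25, 0.75))) - 15), 1)
  expect_lte(abs(diff(quantile(ch$nihss, c(0.25, 0.75))) - 5), 1)
  vif <- compute_vif(ch[cohort_features()])
  expect_true(all(vif$vif < 1.91))
  expect_true(all(vif$vif >= 1))
})

test_that("forced marginal failures are flagged", {
  spec <- cohort_spec(n_subjects = 500, missing_rate = 0, seed = 3)
  ch <- generate_cohort(spec)
  ch$sex <- 1  # all male vs target 118/314
  rep <- validate_marginals(ch, spec)
  expect_false(rep$pass[rep$feature == "sex"])
})

test_that("outcome prevalence converges to the planted model's expectation", {
  spec <- cohort_spec(n_subjects = 50000, missing_rate = 0, seed = 11)
  ch <- generate_cohort(spec)
  # oracle: average planted logistic probability over the generated features
  truth <- attr(ch, "truth")
  Xs <- sweep(as.matrix(ch[cohort_features()]), 2,
              truth$moments$mean[cohort_features()], "-")
  Xs <- sweep(Xs, 2, truth$moments$sd[cohort_features()], "/")
  p_expected <- mean(plogis(truth$intercept +
                              drop(Xs %*% truth$coefficients)))
  p_observed <- mean(dichotomize_mrs(ch$mrs))
  mc_err <- 3 * sqrt(p_expected * (1 - p_expected) / nrow(ch))
  expect_lt(abs(p_observed - p_expected), mc_err + 0.002)
  # and the calibrated intercept targets the study prevalence
  expect_lt(abs(p_expected - 88 / 314), 0.02)
})

test_that("missingness stays at the configured MCAR rate", {
  spec <- cohort_spec(n_subjects = 20000, missing_rate = 0.05, seed = 5)
  ch <- generate_cohort(spec)
  rate <- mean(is.na(as.matrix(ch[cohort_features()])))
  expect_lt(abs(rate - 0.05), 0.005)
  expect_false(anyNA(ch$mrs))
})

test_that("planted_truth_auc behaves as an oracle ceiling", {
  null_spec <- cohort_spec(
    n_subjects = 100, seed = 1,
    planted_coefficients = c(age = 0, sex = 0, nihss = 0, cardiac = 0,
                             diabetes = 0, hypercholesterolemia = 0,
                             thrombolysis = 0))
  expect_lt(abs(planted_truth_auc(null_spec, n_mc = 20000) - 0.5), 0.02)

  strong <- cohort_spec(
    n_subjects = 100, seed = 1,
    planted_coefficients = c(age = 50, sex = 0, nihss = 0, cardiac = 0,
                             diabetes = 0, hypercholesterolemia = 0,
                             thrombolysis = 0))
  expect_gt(planted_truth_auc(strong, n_mc = 20000), 0.99)

  spec <- cohort_spec(seed = 2)
  a1 <- planted_truth_auc(spec, n_mc = 100000, seed = 101)
  a2 <- planted_truth_auc(spec, n_mc = 100000, seed = 202)
  expect_lt(abs(a1 - a2), 0.01)
})

test_that("cohort CSV round-trips with its spec sidecar", {
  spec <- cohort_spec(n_subjects = 60, seed = 9)
  ch <- generate_cohort(spec)
  path <- tempfile(fileext = ".csv")
  write_cohort(ch, path)
  expect_true(file.exists(paste0(path, ".spec.yaml")))
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(ch[names(back)]),
               tolerance = 1e-12, ignore_attr = TRUE)
  spec2 <- attr(back, "spec")
  expect_equal(spec2$intercept, spec$intercept, tolerance = 1e-9)
  expect_identical(generate_cohort(spec2)$mrs, ch$mrs)
  unlink(c(path, paste0(path, ".spec.yaml")))
})
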