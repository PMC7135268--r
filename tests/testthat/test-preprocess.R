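test_that("mRS dichotomization maps 0-2 to good and 3-6 to bad", {
  expect_identical(dichotomize_mrs(c(0, 1, 2)), c(0L, 0L, 0L))
  expect_identical(dichotomize_mrs(c(3, 4, 5, 6)), c(1L, 1L, 1L, 1L))
  expect_error(dichotomize_mrs(7), "mRS")
  expect_error(dichotomize_mrs(c(2, NA)), "mRS")
  expect_error(dichotomize_mrs(-1), "mRS")
})

test_that("train/test split is a seeded 4:1 partition", {
  s <- split_train_test(314, seed = 1)
  expect_length(s$test, 63)   # round(314 / 5)
  expect_length(s$train, 251)
  expect_setequal(c(s$train, s$test), 1:314)
  expect_length(intersect(s$train, s$test), 0)
  expect_identical(s, split_train_test(314, seed = 1))
  expect_false(identical(s$test, split_train_test(314, seed = 2)$test))

  tiny <- split_train_test(5, seed = 3)
  expect_length(tiny$train, 4)
  expect_length(tiny$test, 1)
  expect_error(split_train_test(4, seed = 1), "at least 5")
})

test_that("preprocessing standardizes with train-only statistics", {
  tr <- data.frame(a = c(1, 2, 3), b = c(1, 1, 0))
  st <- fit_preprocess(tr)
  Z <- apply_preprocess(st, tr)
  expect_equal(Z[, "a"], c(-1, 0, 1) * 1.2247449, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(colMeans(Z), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(sqrt(colMeans(Z^2)), c(a = 1, b = 1), tolerance = 1e-12)

  # binary missing entries take the train mode, continuous the train mean
  tr2 <- data.frame(a = c(1, 2, NA, 3), b = c(1, 1, 0, NA))
  st2 <- fit_preprocess(tr2)
  expect_equal(unname(st2$impute["a"]), 2)
  expect_equal(unname(st2$impute["b"]), 1)

  # applied to new data, the columns need not be centered
  te <- data.frame(a = c(10, 20), b = c(1, 1))
  expect_gt(mean(apply_preprocess(st, te)[, "a"]), 1)
})

test_that("preprocessing state ignores anything outside the training rows", {
  spec <- cohort_spec(n_subjects = 100, seed = 21)
  ch <- as.data.frame(generate_cohort(spec))[cohort_features()]
  idx <- split_train_test(100, seed = 2)
  st1 <- fit_preprocess(ch[idx$train, ])
  ch2 <- ch
  ch2[idx$test, "age"] <- 999  # perturb test rows only
  st2 <- fit_preprocess(ch2[idx$train, ])
  expect_identical(st1, st2)
})

test_that("zero-variance training columns are rejected", {
  expect_error(fit_preprocess(data.frame(a = c(1, 1, 1), b = c(0, 1, 0))),
               "Zero-variance")
})

test_that("balance subsampling equalizes class counts exactly", {
  labels <- c(rep(1, 88), rep(0, 226))
  keep <- subsample_balance(labels, seed = 4)
  expect_length(keep, 176)
  expect_equal(sum(labels[keep] == 1), 88)
  expect_equal(sum(labels[keep] == 0), 88)
  expect_true(all(which(labels == 1) %in% keep))
  expect_identical(keep, subsample_balance(labels, seed = 4))

  balanced <- rep(c(0, 1), each = 10)
  expect_identical(subsample_balance(balanced, 1), 1:20)
  expect_error(subsample_balance(rep(1, 10), 1), "Both classes")
})

test_that("VIF matches the normal-equations oracle and its invariants", {
  set.seed(31)
  n <- 300
  Z <- matrix(rnorm(n * 7), n, 7)
  X <- Z %*% chol(0.3 + 0.7 * diag(7))  # correlated 7-column design
  colnames(X) <- paste0("x", 1:7)
  vif <- compute_vif(X)
  expect_equal(vif$vif, vif_oracle(X), tolerance = 1e-9)
  expect_true(all(vif$vif >= 1))

  # permuting feature order permutes the VIFs identically
  perm <- c(3, 1, 7, 2, 6, 4, 5)
  vif_p <- compute_vif(X[, perm])
  expect_equal(vif_p$vif, vif$vif[perm], tolerance = 1e-9)

  # centered orthogonal columns give VIF 1; a duplicate is flagged infinite
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(50 * 3), 50, 3))))[, 2:4]
  expect_equal(compute_vif(Q)$vif, rep(1, 3), tolerance = 1e-9)
  dup <- cbind(X[, 1:2], X[, 1])
  vif_d <- compute_vif(dup)
  expect_true(all(vif_d$aliased[c(1, 3)]))
  expect_true(all(is.infinite(vif_d$vif[c(1, 3)])))
})
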