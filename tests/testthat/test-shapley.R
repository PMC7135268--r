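test_that("additive models yield the closed-form Shapley values", {
  cf <- c(2, -1, 0.5)
  predict_lin <- function(X) drop(X %*% cf)
  set.seed(1)
  bg <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, paste0("x", 1:3)))
  x <- c(1, 2, -1)
  phi <- exact_shapley(predict_lin, x, bg)
  expect_equal(as.numeric(phi), unname(cf * (x - colMeans(bg))),
               tolerance = 1e-9)

  # |F| = 2 case checked fully by hand
  bg2 <- rbind(c(0, 0), c(2, 4))
  phi2 <- exact_shapley(function(X) drop(X %*% c(1, 3)), c(1, 1), bg2)
  expect_equal(as.numeric(phi2), c(1 * (1 - 1), 3 * (1 - 2)),
               tolerance = 1e-12)
})

test_that("the dummy axiom holds for a feature the model never reads", {
  ens <- random_tree_ensemble(p = 7, n_trees = 4, depth = 2, seed = 2)
  # rewrite every split to avoid feature 7
  ens$trees <- lapply(ens$trees, function(tr) {
    tr[tr[, "feature"] == 7, "feature"] <- 1
    tr
  })
  set.seed(3)
  bg <- matrix(rnorm(70), 10, 7, dimnames = list(NULL, paste0("x", 1:7)))
  phi <- exact_shapley(function(X) predict_proba(ens, X), rnorm(7), bg)
  expect_equal(unname(phi["x7"]), 0, tolerance = 1e-12)
})

test_that("efficiency, symmetry and linearity hold on tree ensembles", {
  set.seed(4)
  for (rep_i in 1:5) {
    ens <- random_tree_ensemble(p = 7, n_trees = 5, depth = 2,
                                seed = 10 + rep_i)
    bg <- matrix(rnorm(70), 10, 7, dimnames = list(NULL, paste0("x", 1:7)))
    x <- rnorm(7)
    f <- function(X) predict_proba(ens, X)
    phi <- exact_shapley(f, x, bg)
    expect_equal(sum(phi), attr(phi, "fx") - attr(phi, "f0"),
                 tolerance = 1e-9)

    # linearity: Shapley of a sum of two models is the sum of Shapleys
    ens2 <- random_tree_ensemble(p = 7, n_trees = 3, depth = 2,
                                 seed = 40 + rep_i)
    g <- function(X) predict_proba(ens2, X)
    phi_sum <- exact_shapley(function(X) f(X) + g(X), x, bg)
    expect_equal(as.numeric(phi_sum),
                 as.numeric(phi) + as.numeric(exact_shapley(g, x, bg)),
                 tolerance = 1e-9)
  }

  # symmetry: a model exchangeable in features 1 and 2, identical background
  # columns and identical x values gives them equal attributions
  f_sym <- function(X) plogis(X[, 1] + X[, 2] + 0.5 * X[, 3] * X[, 1])
  set.seed(5)
  bg <- matrix(rnorm(30), 10, 3)
  bg[, 2] <- bg[, 1]
  f_sym2 <- function(X) plogis(X[, 1] + X[, 2] +
                                 0.25 * X[, 3] * (X[, 1] + X[, 2]))
  phi <- exact_shapley(f_sym2, c(1.3, 1.3, -0.2), bg)
  expect_equal(unname(phi[1]), unname(phi[2]), tolerance = 1e-9)
})

test_that("enumeration agrees with the permutation-sampling oracle", {
  ens <- random_tree_ensemble(p = 5, n_trees = 4, depth = 2, seed = 6)
  set.seed(7)
  bg <- matrix(rnorm(50), 10, 5, dimnames = list(NULL, paste0("x", 1:5)))
  x <- rnorm(5)
  f <- function(X) predict_proba(ens, X)
  phi <- exact_shapley(f, x, bg)
  orc <- permutation_shapley_oracle(f, x, bg, n_perm = 4000, seed = 8)
  expect_true(all(abs(as.numeric(phi) - orc$phi) <=
                    pmax(4 * orc$se, 1e-12)))
})

test_that("inputs are validated", {
  bg <- matrix(rnorm(20), 10, 2)
  expect_error(exact_shapley(function(X) X[, 1], c(1, 2),
                             bg[0, , drop = FALSE]), "non-empty")
  expect_error(exact_shapley(function(X) X[, 1], 1:16,
                             matrix(rnorm(32), 2, 16)), "15 features")
  expect_error(aggregate_shap(matrix(numeric(0), 0, 3)), "at least one")
})

test_that("aggregation is the signed column mean", {
  set.seed(9)
  phis <- matrix(rnorm(140), 20, 7, dimnames = list(NULL, paste0("x", 1:7)))
  agg <- aggregate_shap(phis)
  expect_equal(as.numeric(agg), unname(colMeans(phis)), tolerance = 1e-12)
  # exact cancellation under the signed mean
  two <- rbind(c(0.4, 1), c(-0.4, 1))
  expect_equal(as.numeric(aggregate_shap(two)), c(0, 1))
  one <- matrix(c(0.1, 0.2), 1)
  expect_equal(as.numeric(aggregate_shap(one)), c(0.1, 0.2))
})
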