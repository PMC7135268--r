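test_that("a single binary split separates a deterministic outcome", {
  set.seed(1)
  X <- cbind(x1 = rbinom(100, 1, 0.5), x2 = rnorm(100))
  y <- X[, "x1"]
  fit <- fit_gbdt(X, y, gbdt_hyper(depth = 1, n_trees = 5,
                                   bagging_temperature = 0,
                                   l2_leaf_reg = 0), seed = 1)
  expect_equal(roc_auc(predict_proba(fit, X), y), 1)
})

test_that("zero learning rate predicts the base rate everywhere", {
  set.seed(2)
  X <- matrix(rnorm(200), 100, 2)
  y <- rbinom(100, 1, 0.3)
  fit <- fit_gbdt(X, y, gbdt_hyper(learning_rate = 0, n_trees = 10,
                                   early_stopping_rounds = 0), seed = 1)
  expect_equal(predict_proba(fit, X), rep(mean(y), 100), tolerance = 1e-9)
})

test_that("one depth-1 tree reproduces the closed-form Newton leaf values", {
  # 6-row dataset split exactly by x <= 0.5
  X <- matrix(c(0, 0, 0, 1, 1, 1), ncol = 1,
              dimnames = list(NULL, "x1"))
  y <- c(0, 0, 1, 1, 1, 1)
  fit <- fit_gbdt(X, y, gbdt_hyper(depth = 1, n_trees = 1, l2_leaf_reg = 0,
                                   bagging_temperature = 0,
                                   leaf_estimation_iterations = 1,
                                   learning_rate = 1), seed = 1)
  # hand computation: p0 = mean(y); per-leaf Newton step -sum(g)/sum(h)
  p0 <- mean(y)
  g <- p0 - y
  h <- rep(p0 * (1 - p0), 6)
  left <- X[, 1] <= 0.5
  w_left <- -sum(g[left]) / sum(h[left])
  w_right <- -sum(g[!left]) / sum(h[!left])
  margin <- qlogis(p0) + ifelse(left, w_left, w_right)
  expect_equal(predict_proba(fit, X), plogis(margin), tolerance = 1e-9)
})

test_that("training loss is non-increasing with unit observation weights", {
  set.seed(3)
  X <- matrix(rnorm(600), 200, 3)
  y <- as.numeric(runif(200) < plogis(X[, 1] - X[, 2]))
  fit <- fit_gbdt(X, y, gbdt_hyper(depth = 2, n_trees = 50,
                                   bagging_temperature = 0,
                                   learning_rate = 0.1,
                                   early_stopping_rounds = 0), seed = 1)
  expect_true(all(diff(fit$train_loss) <= 1e-10))
})

test_that("prediction equals the sigmoid of summed traversed leaf scores", {
  # two hand-built trees: tree 1 splits on x1 at 0, tree 2 on x2 at 1
  t1 <- rbind(c(1, 0, 2, 3, 0), c(0, 0, 0, 0, -1), c(0, 0, 0, 0, 2))
  t2 <- rbind(c(2, 1, 2, 3, 0), c(0, 0, 0, 0, 0.5), c(0, 0, 0, 0, -0.25))
  ens <- new_tree_ensemble(list(t1, t2), base_score = 0.1,
                           learning_rate = 0.5, features = c("x1", "x2"))
  X <- rbind(c(-1, 0), c(1, 2), c(0, 5))
  # manual traversal: rows fall left/right by the two thresholds
  expected_margin <- 0.1 + 0.5 * c(-1 + 0.5, 2 + (-0.25), -1 + (-0.25))
  expect_equal(gbdt_margin(ens, X), expected_margin, tolerance = 1e-12)
  expect_equal(predict_proba(ens, X), plogis(expected_margin))
})

test_that("all-constant features produce an intercept-only ensemble", {
  X <- matrix(1, 50, 2)
  y <- rep(c(0, 1), 25)
  fit <- fit_gbdt(X, y, gbdt_hyper(n_trees = 3,
                                   early_stopping_rounds = 0), seed = 1)
  expect_equal(length(unique(predict_proba(fit, X))), 1)
})

test_that("leaf estimation iterations refine toward the unpenalized optimum", {
  set.seed(4)
  X <- cbind(x1 = rbinom(80, 1, 0.5))
  y <- as.numeric(runif(80) < ifelse(X[, 1] == 1, 0.9, 0.2))
  p1 <- fit_gbdt(X, y, gbdt_hyper(depth = 1, n_trees = 1, l2_leaf_reg = 0,
                                  bagging_temperature = 0, learning_rate = 1,
                                  leaf_estimation_iterations = 1), seed = 1)
  p5 <- fit_gbdt(X, y, gbdt_hyper(depth = 1, n_trees = 1, l2_leaf_reg = 0,
                                  bagging_temperature = 0, learning_rate = 1,
                                  leaf_estimation_iterations = 5), seed = 1)
  # with more Newton steps the leaf probabilities approach the leaf means
  target <- ifelse(X[, 1] == 1, mean(y[X[, 1] == 1]), mean(y[X[, 1] == 0]))
  err1 <- max(abs(predict_proba(p1, X) - target))
  err5 <- max(abs(predict_proba(p5, X) - target))
  expect_lt(err5, err1)
  expect_lt(err5, 1e-3)
})

test_that("fits are deterministic given data, hyperparameters and seed", {
  set.seed(5)
  X <- matrix(rnorm(300), 100, 3)
  y <- rbinom(100, 1, 0.4)
  h <- gbdt_hyper(n_trees = 20)
  a <- fit_gbdt(X, y, h, seed = 9)
  b <- fit_gbdt(X, y, h, seed = 9)
  expect_identical(a$trees, b$trees)
  c_ <- fit_gbdt(X, y, h, seed = 10)
  expect_false(identical(a$trees, c_$trees))
})
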