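test_that("relevance is conserved and non-negative on non-negative inputs", {
  for (i in 1:10) {
    m <- random_mlp(p = 7, hidden = 5 + (i %% 16), seed = 100 + i)
    x <- abs(rnorm(7))
    r <- lrp_deep_taylor(m, x)
    hidden_active <- sum(r$hidden) > 0
    if (hidden_active) {
      expect_equal(sum(r$input), r$output, tolerance = 1e-9)
    }
    expect_true(all(r$input >= 0))
    expect_true(all(r$hidden >= 0))
  }
})

test_that("the printed rule splits relevance by positive-weighted activation", {
  # one hidden neuron, inputs a = (1, 3), positive unit weights
  m <- structure(list(W1 = matrix(c(1, 1), 2, 1), b1 = 0,
                      W2 = matrix(c(0, 1), 1, 2), b2 = c(0, 0),
                      dropout_rate = 0, l1_ratio = 0,
                      features = c("a", "b")),
                 class = c("mlp_params", "stroke_model"))
  r <- lrp_deep_taylor(m, c(1, 3))
  expect_equal(unname(r$input / r$output), c(0.25, 0.75), tolerance = 1e-12)
})

test_that("an identity-like hidden layer routes all relevance to one input", {
  # hidden layer passes input 1 through; input 2 is disconnected
  m <- structure(list(W1 = matrix(c(1, 0), 2, 1), b1 = 0,
                      W2 = matrix(c(0, 2), 1, 2), b2 = c(0, 0),
                      dropout_rate = 0, l1_ratio = 0,
                      features = c("a", "b")),
                 class = c("mlp_params", "stroke_model"))
  r <- lrp_deep_taylor(m, c(1.5, 7))
  expect_equal(unname(r$input["a"]), r$output, tolerance = 1e-12)
  expect_equal(unname(r$input["b"]), 0)
})

test_that("seeding class can decompose P(bad) or the predicted class", {
  m <- random_mlp(p = 4, hidden = 6, seed = 3)
  x <- abs(rnorm(4))
  p_bad <- predict_proba(m, matrix(x, 1))
  r_bad <- lrp_deep_taylor(m, x, class_neuron = "bad")
  expect_equal(r_bad$output, unname(p_bad), tolerance = 1e-12)
  expect_equal(r_bad$seed_class, 1L)
  r_pred <- lrp_deep_taylor(m, x, class_neuron = "predicted")
  expect_equal(r_pred$output, max(p_bad, 1 - p_bad), tolerance = 1e-12)
})

test_that("confidence weights follow theta = y*P + (1-y)*(1-P)", {
  rel <- matrix(1, 2, 3)
  r1 <- confidence_weighted_rating(rel[1, , drop = FALSE], 0.9, 1)
  expect_equal(as.numeric(r1), rep(0.9, 3))
  r0 <- confidence_weighted_rating(rel[1, , drop = FALSE], 0.9, 0)
  expect_equal(as.numeric(r0), rep(0.1, 3), tolerance = 1e-12)
})

test_that("rating equals a hand-computed confidence-weighted mean", {
  set.seed(4)
  rel <- matrix(rnorm(10 * 7), 10, 7)
  P <- runif(10)
  y <- rbinom(10, 1, 0.5)
  out <- confidence_weighted_rating(rel, P, y)
  theta <- y * P + (1 - y) * (1 - P)
  manual <- vapply(1:7, function(f) sum(theta * rel[, f]) / 10, numeric(1))
  expect_equal(as.numeric(out), manual, tolerance = 1e-12)
  # all-confident, all-correct weighting reduces to the plain average
  plain <- confidence_weighted_rating(rel, rep(1, 10), rep(1, 10))
  expect_equal(as.numeric(plain), colMeans(rel), tolerance = 1e-12)
})

test_that("degenerate inputs are rejected", {
  m <- random_mlp(p = 3, hidden = 4, seed = 5)
  expect_error(lrp_deep_taylor(m, c(1, 2)), "input size")
  expect_error(confidence_weighted_rating(matrix(1, 2, 2), c(0.5), c(1, 0)),
               "aligned")
  expect_error(confidence_weighted_rating(matrix(1, 2, 2), c(0.5, 1.5),
                                          c(1, 0)), "0, 1")
})
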