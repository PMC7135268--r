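# Independent oracles used across the suite.  Each is coded from the
# definition, sharing no internals with the package implementation.

# Shapley values by sampling random feature orderings: for each permutation,
# each feature's marginal contribution when added to the preceding set.
# Returns the estimate and its per-feature Monte-Carlo standard error.
permutation_shapley_oracle <- function(predict_fun, x, background,
                                       n_perm = 2000, seed = 1) {
  p <- length(x)
  nb <- nrow(background)
  value_of <- function(S) {
    Xb <- background
    if (length(S)) Xb[, S] <- matrix(x[S], nb, length(S), byrow = TRUE)
    mean(predict_fun(Xb))
  }
  # cache coalition values by key so repeated prefixes are cheap
  cache <- new.env(parent = emptyenv())
  v <- function(S) {
    key <- paste0("k", paste(sort(S), collapse = ","))
    if (is.null(cache[[key]])) cache[[key]] <- value_of(S)
    cache[[key]]
  }
  contrib <- matrix(0, n_perm, p)
  set.seed(seed)
  for (r in seq_len(n_perm)) {
    ord <- sample.int(p)
    prev <- numeric(0)
    v_prev <- v(prev)
    for (j in ord) {
      cur <- c(prev, j)
      v_cur <- v(cur)
      contrib[r, j] <- v_cur - v_prev
      prev <- cur
      v_prev <- v_cur
    }
  }
  list(phi = colMeans(contrib),
       se = apply(contrib, 2, stats::sd) / sqrt(n_perm))
}

# VIF from explicit normal-equations least squares
vif_oracle <- function(X) {
  vapply(seq_len(ncol(X)), function(j) {
    yj <- X[, j]
    Z <- cbind(1, X[, -j, drop = FALSE])
    beta <- solve(t(Z) %*% Z, t(Z) %*% yj)
    res <- yj - Z %*% beta
    r2 <- 1 - sum(res^2) / sum((yj - mean(yj))^2)
    1 / (1 - r2)
  }, numeric(1))
}

# quantile by explicit linear interpolation between order statistics
# (the convention with h = (n - 1) * p + 1)
quantile_oracle <- function(x, probs) {
  xs <- sort(x)
  n <- length(xs)
  vapply(probs, function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    xs[lo] + (h - lo) * (xs[hi] - xs[lo])
  }, numeric(1))
}

# AUC by brute-force enumeration of positive-negative pairs, ties = 1/2
auc_pairs_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# a random depth-limited tree over p features as a node matrix
random_tree <- function(p, depth = 2, seed) {
  set.seed(seed)
  nodes <- NULL
  grow <- function(d) {
    id <- nrow(nodes %||% matrix(0, 0, 5)) + 1
    nodes <<- rbind(nodes, c(0, 0, 0, 0, 0))
    if (d < depth && runif(1) < 0.8) {
      f <- sample.int(p, 1)
      thr <- rnorm(1)
      l <- grow(d + 1)
      r <- grow(d + 1)
      nodes[id, ] <<- c(f, thr, l, r, 0)
    } else {
      nodes[id, 5] <<- rnorm(1)
    }
    id
  }
  grow(0)
  colnames(nodes) <- c("feature", "threshold", "left", "right", "value")
  nodes
}

random_tree_ensemble <- function(p = 7, n_trees = 5, depth = 2, seed = 1) {
  trees <- lapply(seq_len(n_trees),
                  function(k) random_tree(p, depth, seed * 1000 + k))
  new_tree_ensemble(trees, base_score = 0, learning_rate = 1,
                    features = paste0("x", seq_len(p)))
}

# a random rectifier MLP without training (for propagation-rule tests)
random_mlp <- function(p = 7, hidden = 10, seed = 1, dropout = 0) {
  set.seed(seed)
  structure(list(W1 = matrix(rnorm(p * hidden), p, hidden),
                 b1 = rnorm(hidden, sd = 0.1),
                 W2 = matrix(rnorm(hidden * 2), hidden, 2),
                 b2 = rnorm(2, sd = 0.1),
                 dropout_rate = dropout, l1_ratio = 0,
                 features = paste0("x", seq_len(p))),
            class = c("mlp_params", "stroke_model"))
}

# small standardized design + logistic outcome for model tests
make_toy_data <- function(n, beta, intercept = 0, seed = 1) {
  set.seed(seed)
  p <- length(beta)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("x", seq_len(p))
  y <- as.numeric(runif(n) < plogis(intercept + drop(X %*% beta)))
  list(X = X, y = y)
}

# compact reduced grid used by pipeline-level tests
tiny_grid <- function() {
  structure(list(
    lasso = list(C = 1),
    elastic_net = list(l1_ratio = 0.5, alpha = 0.0025),
    gbdt = list(depth = 2, learning_rate = 0.1, bagging_temperature = 1,
                l2_leaf_reg = 3, leaf_estimation_iterations = 1,
                n_trees = 60),
    mlp = list(hidden_units = 10, learning_rate = 0.01, batch_size = 32,
               dropout_rate = 0.1, l1_ratio = 1e-4, epochs = 150)),
    class = "hyper_grid")
}
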