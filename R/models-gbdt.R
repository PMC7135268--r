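# Gradient-boosted decision trees with logistic loss, written from scratch:
# stagewise fitting of depth-limited regression trees to the current negative
# gradients, greedy variance-reducing axis-aligned splits, L2-regularized
# Newton leaf estimates (optionally refined over several Newton iterations),
# and a bagging-temperature-controlled Bayesian-bootstrap reweighting of
# observations per tree.  The regularizer is gamma * T + lambda/2 * ||w||^2
# over leaf count T and leaf weights w; gamma defaults to 0.

#' GBDT hyperparameters
#'
#' @param depth Maximum tree depth (root = depth 0 splits).
#' @param learning_rate Shrinkage applied to each tree's leaf scores.
#' @param bagging_temperature `t >= 0`; per-tree observation weights are
#'   `u^t` with `u` standard exponential (normalized to mean 1).  `t = 0`
#'   gives unit weights.
#' @param l2_leaf_reg L2 penalty `lambda` on leaf values.
#' @param leaf_estimation_iterations Newton refinements of the leaf values
#'   under the fixed tree structure.
#' @param n_trees Maximum number of boosting stages.
#' @param gamma Per-leaf complexity penalty (default 0; a split must improve
#'   the regularized objective by more than `gamma` to be kept).
#' @param early_stopping_rounds Stop when the training loss has improved by
#'   less than `tol` over this many consecutive stages (`0` disables).
#' @param tol Relative training-loss improvement threshold for early stop.
#' @return A list of class `gbdt_hyper`.
#' @export
gbdt_hyper <- function(depth = 4, learning_rate = 0.1,
                       bagging_temperature = 1, l2_leaf_reg = 3,
                       leaf_estimation_iterations = 1, n_trees = 200,
                       gamma = 0, early_stopping_rounds = 20, tol = 1e-5) {
  structure(list(depth = depth, learning_rate = learning_rate,
                 bagging_temperature = bagging_temperature,
                 l2_leaf_reg = l2_leaf_reg,
                 leaf_estimation_iterations = leaf_estimation_iterations,
                 n_trees = n_trees, gamma = gamma,
                 early_stopping_rounds = early_stopping_rounds, tol = tol),
            class = "gbdt_hyper")
}

# grow one regression tree on (gradient, hessian) pairs; returns the flat
# node matrix (see src/gbdt.cpp for the column layout) plus per-row leaf ids
grow_tree <- function(X, g, h, depth_max, lambda, gamma) {
  n <- nrow(X)
  nodes <- list()   # each: c(feature, threshold, left, right, value)
  leaf_rows <- list()
  new_node <- function() {
    nodes[[length(nodes) + 1]] <<- c(0, 0, 0, 0, 0)
    length(nodes)
  }
  score <- function(G, H) G^2 / (H + lambda)
  build <- function(idx, depth) {
    id <- new_node()
    G <- sum(g[idx]); H <- sum(h[idx])
    best <- list(gain = 0)
    if (depth < depth_max && length(idx) >= 2) {
      for (j in seq_len(ncol(X))) {
        x <- X[idx, j]
        ord <- order(x)
        xs <- x[ord]
        cut_ok <- which(xs[-length(xs)] < xs[-1])
        if (!length(cut_ok)) next
        cg <- cumsum(g[idx][ord]); ch <- cumsum(h[idx][ord])
        GL <- cg[cut_ok]; HL <- ch[cut_ok]
        gain <- 0.5 * (score(GL, HL) + score(G - GL, H - HL) -
                         score(G, H)) - gamma
        b <- which.max(gain)
        if (gain[b] > best$gain + 1e-12) {
          best <- list(gain = gain[b], feature = j,
                       threshold = (xs[cut_ok[b]] + xs[cut_ok[b] + 1]) / 2,
                       left = idx[ord[seq_len(cut_ok[b])]],
                       right = idx[ord[-seq_len(cut_ok[b])]])
        }
      }
    }
    if (best$gain > 0) {
      l <- build(best$left, depth + 1)
      r <- build(best$right, depth + 1)
      nodes[[id]] <<- c(best$feature, best$threshold, l, r, 0)
    } else {
      leaf_rows[[id]] <<- idx
    }
    id
  }
  build(seq_len(n), 0)
  mat <- do.call(rbind, nodes)
  colnames(mat) <- c("feature", "threshold", "left", "right", "value")
  leaf_of_row <- integer(n)
  for (id in seq_along(leaf_rows)) {
    if (!is.null(leaf_rows[[id]])) leaf_of_row[leaf_rows[[id]]] <- id
  }
  list(mat = mat, leaf_of_row = leaf_of_row)
}

#' Fit a gradient-boosted decision tree classifier
#'
#' Stagewise gradient boosting on the logistic loss.  Each stage fits a
#' depth-limited regression tree to the current negative gradients with
#' greedy variance-reducing splits, computes leaf values by L2-regularized
#' Newton steps (refined `leaf_estimation_iterations` times), and adds the
#' tree with `learning_rate` shrinkage.  Observation weights for each tree
#' are drawn by a bagging-temperature Bayesian-bootstrap scheme.
#'
#' @inheritParams fit_glm
#' @param hyper A [gbdt_hyper()] configuration.
#' @param seed Integer seed driving the per-tree bagging weights.
#' @return An object of class `tree_ensemble`.
#' @export
fit_gbdt <- function(X, y, hyper = gbdt_hyper(), seed = 1L) {
  X <- check_xy(X, y)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  lambda <- hyper$l2_leaf_reg
  base_score <- qlogis(min(max(mean(y), 1e-6), 1 - 1e-6))
  margin <- rep(base_score, n)
  trees <- vector("list", hyper$n_trees)
  losses <- numeric(hyper$n_trees)
  logloss <- function(m) {
    p <- pmin(pmax(plogis(m), 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  k_used <- 0L
  with_seed(seed, {
    for (k in seq_len(hyper$n_trees)) {
      wts <- if (hyper$bagging_temperature > 0) {
        u <- rexp(n)^hyper$bagging_temperature
        u / mean(u)
      } else rep(1, n)
      p <- plogis(margin)
      g <- (p - y) * wts
      h <- pmax(p * (1 - p), 1e-12) * wts
      tr <- grow_tree(X, g, h, hyper$depth, lambda, hyper$gamma)
      leaf_ids <- sort(unique(tr$leaf_of_row))
      w_leaf <- stats::setNames(numeric(length(leaf_ids)),
                                leaf_ids)
      for (it in seq_len(hyper$leaf_estimation_iterations)) {
        m2 <- margin + w_leaf[as.character(tr$leaf_of_row)]
        p2 <- plogis(m2)
        g2 <- (p2 - y) * wts
        h2 <- pmax(p2 * (1 - p2), 1e-12) * wts
        for (lid in leaf_ids) {
          rows <- tr$leaf_of_row == lid
          key <- as.character(lid)
          G <- sum(g2[rows]) + lambda * w_leaf[key]
          H <- sum(h2[rows]) + lambda
          w_leaf[key] <- w_leaf[key] - G / H
        }
      }
      mat <- tr$mat
      mat[leaf_ids, "value"] <- w_leaf[as.character(leaf_ids)]
      trees[[k]] <- mat
      margin <- margin +
        hyper$learning_rate * mat[tr$leaf_of_row, "value"]
      losses[k] <- logloss(margin)
      k_used <- k
      r <- hyper$early_stopping_rounds
      if (r > 0 && k > r) {
        if (losses[k - r] - losses[k] < hyper$tol * max(1, losses[k - r])) {
          break
        }
      }
    }
  })
  structure(list(trees = trees[seq_len(k_used)], base_score = base_score,
                 learning_rate = hyper$learning_rate, hyper = hyper,
                 features = colnames(X),
                 train_loss = losses[seq_len(k_used)], seed = seed),
            class = c("tree_ensemble", "stroke_model"))
}

#' Construct a tree ensemble from explicit node matrices
#'
#' Low-level constructor used for hand-built ensembles (audit, testing,
#' serialization round-trips).  Each tree is a node matrix with columns
#' `feature` (1-based split feature; 0 = leaf), `threshold` (left branch
#' when `x <= threshold`), `left`, `right` (1-based child rows) and `value`
#' (leaf score).
#'
#' @param trees List of node matrices.
#' @param base_score Initial margin (log-odds).
#' @param learning_rate Shrinkage applied to leaf scores.
#' @param features Character vector of feature names.
#' @return A `tree_ensemble`.
#' @export
new_tree_ensemble <- function(trees, base_score = 0, learning_rate = 1,
                              features) {
  structure(list(trees = trees, base_score = base_score,
                 learning_rate = learning_rate, hyper = NULL,
                 features = features, train_loss = numeric(0), seed = NA),
            class = c("tree_ensemble", "stroke_model"))
}

#' Ensemble margin (log-odds before the sigmoid)
#' @param model A `tree_ensemble`.
#' @param X Numeric feature matrix.
#' @return Numeric margin vector.
#' @export
gbdt_margin <- function(model, X) {
  X <- as_feature_matrix(X)
  if (ncol(X) != length(model$features)) {
    abort("`X` column count does not match the ensemble's feature count.")
  }
  gbdt_margin_cpp(X, model$trees, model$base_score, model$learning_rate)
}

#' @export
predict_proba.tree_ensemble <- function(model, X, ...) {
  plogis(gbdt_margin(model, X))
}

#' @export
print.tree_ensemble <- function(x, ...) {
  cat("<tree_ensemble>", length(x$trees), "trees | base score",
      signif(x$base_score, 4), "| learning rate", x$learning_rate, "\n")
  invisible(x)
}

#' @export
glance.tree_ensemble <- function(x, ...) {
  tibble::tibble(n_trees = length(x$trees),
                 depth = x$hyper$depth %||% NA_real_,
                 learning_rate = x$learning_rate,
                 l2_leaf_reg = x$hyper$l2_leaf_reg %||% NA_real_,
                 final_train_loss = if (length(x$train_loss))
                   x$train_loss[length(x$train_loss)] else NA_real_)
}
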