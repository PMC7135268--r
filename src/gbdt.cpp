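#include <Rcpp.h>
using namespace Rcpp;

// Margin (log-odds) of a boosted tree ensemble.
// Each tree is a numeric matrix with one row per node and columns
//   0: split feature (1-based; 0 marks a leaf)
//   1: threshold (go left when x <= threshold)
//   2: left child (1-based row index)
//   3: right child (1-based row index)
//   4: leaf value (log-odds increment, pre learning-rate)
// [[Rcpp::export]]
NumericVector gbdt_margin_cpp(NumericMatrix X, List trees,
                              double base_score, double learning_rate) {
  const int n = X.nrow();
  NumericVector out(n, base_score);
  const int K = trees.size();
  for (int k = 0; k < K; ++k) {
    NumericMatrix tr = trees[k];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (tr(node, 0) > 0.5) {
        int f = (int) tr(node, 0) - 1;
        node = (X(i, f) <= tr(node, 1)) ? (int) tr(node, 2) - 1
                                        : (int) tr(node, 3) - 1;
      }
      out[i] += learning_rate * tr(node, 4);
    }
  }
  return out;
}

// Leaf index (1-based row in the tree matrix) of each observation.
// [[Rcpp::export]]
IntegerVector tree_leaf_index_cpp(NumericMatrix X, NumericMatrix tr) {
  const int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (tr(node, 0) > 0.5) {
      int f = (int) tr(node, 0) - 1;
      node = (X(i, f) <= tr(node, 1)) ? (int) tr(node, 2) - 1
                                      : (int) tr(node, 3) - 1;
    }
    out[i] = node + 1;
  }
  return out;
}
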