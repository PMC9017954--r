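#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Average path length of an unsuccessful BST search among n points; the
// isolation-forest normalising constant.
static double avg_path(double n) {
  if (n <= 1.0) return 0.0;
  const double euler = 0.5772156649015329;
  return 2.0 * (std::log(n - 1.0) + euler) - 2.0 * (n - 1.0) / n;
}

// Anomaly scores in (0, 1): s = 2^(-E[h(x)] / c(psi)). Trees are flat
// arrays: feature (0-based; -1 marks a leaf), split, left/right child
// indices (0-based), and leaf sizes for the path-length adjustment.
// [[Rcpp::export]]
NumericVector iforest_score_cpp(NumericMatrix x, List trees,
                                double subsample) {
  const int n = x.nrow();
  const int ntree = trees.size();
  NumericVector total(n);
  for (int t = 0; t < ntree; ++t) {
    List tree = trees[t];
    IntegerVector feature = tree["feature"];
    NumericVector split = tree["split"];
    IntegerVector left = tree["left"];
    IntegerVector right = tree["right"];
    IntegerVector size = tree["size"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      double depth = 0.0;
      while (feature[node] >= 0) {
        node = (x(i, feature[node]) < split[node]) ? left[node] : right[node];
        depth += 1.0;
      }
      total[i] += depth + avg_path((double)size[node]);
    }
  }
  const double cn = avg_path(subsample);
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = std::pow(2.0, -(total[i] / ntree) / (cn > 0 ? cn : 1.0));
  return out;
}
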