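#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

// Local cost: Euclidean distance between row i of a and row j of b.
static inline double rowdist(const NumericMatrix& a, int i,
                             const NumericMatrix& b, int j) {
  double s = 0.0;
  for (int k = 0; k < a.ncol(); ++k) {
    double d = a(i, k) - b(j, k);
    s += d * d;
  }
  return std::sqrt(s);
}

// Classic dynamic time warping: minimal cumulative Euclidean local cost over
// monotone, continuity-constrained warping paths (steps down, right,
// diagonal). No path-length normalization.
// [[Rcpp::export(name = ".dtw_cpp")]]
double dtw_cpp(NumericMatrix a, NumericMatrix b) {
  const int n = a.nrow(), m = b.nrow();
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> prev(m + 1, inf), cur(m + 1, inf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = inf;
    for (int j = 1; j <= m; ++j) {
      double c = rowdist(a, i - 1, b, j - 1);
      double best = prev[j - 1];
      if (prev[j] < best) best = prev[j];
      if (cur[j - 1] < best) best = cur[j - 1];
      cur[j] = c + best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Pairwise DTW cross-distance matrix; each unordered pair computed once.
// [[Rcpp::export(name = ".dtw_cross_cpp")]]
NumericMatrix dtw_cross_cpp(List series) {
  const int n = series.size();
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    NumericMatrix a = series[i];
    for (int j = i + 1; j < n; ++j) {
      NumericMatrix b = series[j];
      double d = dtw_cpp(a, b);
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}
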