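#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact brute-force k-nearest-neighbor distances.
// Returns an n x kmax matrix: row i holds the sorted distances from point i to
// its kmax nearest neighbors (the point itself excluded). With periodic = true,
// coordinates are assumed to lie in [0,1) and each coordinate difference is
// replaced by its minimum image min(|d|, 1 - |d|) (unit torus).
//
// Approximate search is deliberately not offered: the two-scale estimator uses
// the ratio of consecutive order statistics, which is sensitive to rank errors.
// [[Rcpp::export(name = ".knn_dists_cpp")]]
NumericMatrix knn_dists_cpp(NumericMatrix X, int kmax, bool periodic) {
  const int n = X.nrow(), m = X.ncol();
  if (kmax < 1) stop("kmax must be >= 1");
  if (kmax > n - 1) stop("kmax must be <= n - 1");
  NumericMatrix out(n, kmax);
  // row-major copy so each point is contiguous in memory
  std::vector<double> P((size_t)n * m);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < m; ++c)
      P[(size_t)i * m + c] = X(i, c);
  std::vector<double> d2(n - 1);
  for (int i = 0; i < n; ++i) {
    const double *pi = &P[(size_t)i * m];
    int idx = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double *pj = &P[(size_t)j * m];
      double s = 0.0;
      if (periodic) {
        for (int c = 0; c < m; ++c) {
          double d = std::fabs(pi[c] - pj[c]);
          if (d > 0.5) d = 1.0 - d;
          s += d * d;
        }
      } else {
        for (int c = 0; c < m; ++c) {
          double d = pi[c] - pj[c];
          s += d * d;
        }
      }
      d2[idx++] = s;
    }
    std::partial_sort(d2.begin(), d2.begin() + kmax, d2.end());
    for (int k = 0; k < kmax; ++k) out(i, k) = std::sqrt(d2[k]);
  }
  return out;
}
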