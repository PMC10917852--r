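#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Discrete Frechet distance between two polylines (rows are 3D points):
// the classic O(n m) dynamic program over the coupling grid, where
// ca[i][j] = max(d(P_i, Q_j), min(ca[i-1][j], ca[i-1][j-1], ca[i][j-1])).
// [[Rcpp::export(name = ".frechet_dp")]]
double frechet_dp(NumericMatrix P, NumericMatrix Q) {
  const int n = P.nrow(), m = Q.nrow();
  if (n == 0 || m == 0)
    stop("parameter error: empty polyline");
  std::vector<double> prev(m), cur(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double d = 0.0;
      for (int c = 0; c < 3; ++c) {
        const double diff = P(i, c) - Q(j, c);
        d += diff * diff;
      }
      d = std::sqrt(d);
      double reach;
      if (i == 0 && j == 0)
        reach = d;
      else if (i == 0)
        reach = std::max(cur[j - 1], d);
      else if (j == 0)
        reach = std::max(prev[0], d);
      else {
        double best = std::min(prev[j], std::min(prev[j - 1], cur[j - 1]));
        reach = std::max(best, d);
      }
      cur[j] = reach;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}
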