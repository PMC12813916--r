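#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Classical dynamic-time-warping cumulative cost between two 2-D sequences
// with per-step Euclidean distance, boundary-matched endpoints and no window
// constraint. Two-row rolling dynamic program over raw pointers; the inner
// loop is the hot path of the permutation test.
// [[Rcpp::export]]
double dtw_cost_cpp(NumericVector ax, NumericVector ay,
                    NumericVector bx, NumericVector by) {
  const int n = ax.size(), m = bx.size();
  if (n == 0 || m == 0) stop("empty sequence");
  if (ay.size() != n || by.size() != m) stop("coordinate length mismatch");
  const double *pax = REAL(ax), *pay = REAL(ay);
  const double *pbx = REAL(bx), *pby = REAL(by);
  std::vector<double> row0(m), row1(m);
  double *prev = row0.data(), *cur = row1.data();

  {
    const double ax0 = pax[0], ay0 = pay[0];
    double acc = 0.0;
    for (int j = 0; j < m; ++j) {
      const double dx = ax0 - pbx[j], dy = ay0 - pby[j];
      acc += std::sqrt(dx * dx + dy * dy);
      prev[j] = acc;
    }
  }
  for (int i = 1; i < n; ++i) {
    const double axi = pax[i], ayi = pay[i];
    {
      const double dx = axi - pbx[0], dy = ayi - pby[0];
      cur[0] = prev[0] + std::sqrt(dx * dx + dy * dy);
    }
    double diag = prev[0]; // prev[j-1] carried across iterations
    for (int j = 1; j < m; ++j) {
      const double up = prev[j], left = cur[j - 1];
      double best = diag < up ? diag : up;
      if (left < best) best = left;
      const double dx = axi - pbx[j], dy = ayi - pby[j];
      cur[j] = best + std::sqrt(dx * dx + dy * dy);
      diag = up;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}
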