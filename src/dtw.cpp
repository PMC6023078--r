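#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double local_cost(double u, double v, bool squared) {
  double d = u - v;
  return squared ? d * d : std::fabs(d);
}

// DTW cumulative cost D(a,b) with D(1,1) = d(u1,v1) and the usual
// three-predecessor recurrence. band < 0 means unconstrained; otherwise a
// Sakoe-Chiba band |i - j| <= band (caller guarantees band >= |a - b|).
// [[Rcpp::export]]
double cpp_dtw_cost(NumericVector u, NumericVector v, int band, bool squared) {
  const int a = u.size(), b = v.size();
  std::vector<double> prev(b + 1, R_PosInf), cur(b + 1, R_PosInf);
  prev[0] = 0.0;  // sentinel so D(1,1) = d(u1,v1)
  for (int i = 1; i <= a; ++i) {
    std::fill(cur.begin(), cur.end(), R_PosInf);
    int jlo = 1, jhi = b;
    if (band >= 0) {
      jlo = std::max(1, i - band);
      jhi = std::min(b, i + band);
    }
    for (int j = jlo; j <= jhi; ++j) {
      double m = std::min(prev[j - 1], std::min(prev[j], cur[j - 1]));
      cur[j] = local_cost(u[i - 1], v[j - 1], squared) + m;
    }
    std::swap(prev, cur);
  }
  return prev[b];
}

// Full cumulative-cost matrix, for warp-path backtracking.
// [[Rcpp::export]]
NumericMatrix cpp_dtw_matrix(NumericVector u, NumericVector v, int band,
                             bool squared) {
  const int a = u.size(), b = v.size();
  NumericMatrix D(a, b);
  std::fill(D.begin(), D.end(), R_PosInf);
  for (int i = 0; i < a; ++i) {
    int jlo = 0, jhi = b - 1;
    if (band >= 0) {
      jlo = std::max(0, i - band);
      jhi = std::min(b - 1, i + band);
    }
    for (int j = jlo; j <= jhi; ++j) {
      double m;
      if (i == 0 && j == 0) {
        m = 0.0;
      } else if (i == 0) {
        m = D(0, j - 1);
      } else if (j == 0) {
        m = D(i - 1, 0);
      } else {
        m = std::min(D(i - 1, j - 1), std::min(D(i - 1, j), D(i, j - 1)));
      }
      D(i, j) = local_cost(u[i], v[j], squared) + m;
    }
  }
  return D;
}
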