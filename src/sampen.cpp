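#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// first index idx with r[idx] >= d (idx == nr when d exceeds every
// tolerance); arithmetic guess for uniform grids, always corrected, so
// the result is exact for any sorted grid
static inline int bucket(const std::vector<double>& r, double d,
                         double r0, double inv_dr) {
  const int nr = (int)r.size();
  int idx;
  if (inv_dr > 0.0) {
    idx = (int)((d - r0) * inv_dr);
    if (idx < 0) idx = 0;
    if (idx > nr) idx = nr;
  } else {
    idx = 0;
  }
  while (idx > 0 && r[idx - 1] >= d) --idx;
  while (idx < nr && r[idx] < d) ++idx;
  return idx;
}

static inline double grid_inv_step(const std::vector<double>& r) {
  // reciprocal step for the arithmetic guess; 0 disables it (guess from 0)
  if (r.size() < 2) return 0.0;
  double dr = (r.back() - r.front()) / (double)(r.size() - 1);
  return dr > 0 ? 1.0 / dr : 0.0;
}

// Ordered-pair template match counts for sample entropy, evaluated at a
// whole vector of tolerances in one O(L^2 * m) pass.
//
// Templates of length m and m+1 are both drawn from start positions
// 1..L-m (so the two counts are over the same index range and directly
// comparable in the ratio). Self-matches are excluded; pairs are ordered
// (each unordered pair contributes 2). A pair matches at tolerance r when
// its Chebyshev distance is <= r.
//
// Returns a 2 x length(r_abs) matrix: row 1 = B (length-m matches),
// row 2 = A (length-(m+1) matches). r_abs must be sorted ascending.
// [[Rcpp::export(name = ".sampen_counts")]]
NumericMatrix sampen_counts(NumericVector y, int m, NumericVector r_abs) {
  const int L = y.size();
  const int n = L - m;  // templates per set
  const int nr = r_abs.size();
  if (m < 1) stop("m must be >= 1");
  if (n < 1) stop("series too short: need length(y) - m >= 1");
  for (int k = 1; k < nr; ++k)
    if (r_abs[k] < r_abs[k - 1]) stop("r_abs must be sorted ascending");

  std::vector<double> r(r_abs.begin(), r_abs.end());
  const double r0 = nr ? r[0] : 0.0, inv_dr = grid_inv_step(r);
  const double rmax = nr ? r[nr - 1] : 0.0;
  std::vector<double> binc(nr, 0.0), ainc(nr, 0.0);

  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dm = 0.0;
      bool over = false;
      for (int k = 0; k < m; ++k) {
        double d = std::fabs(y[i + k] - y[j + k]);
        if (d > dm) {
          dm = d;
          if (dm > rmax) { over = true; break; }  // can only grow
        }
      }
      if (over) continue;
      binc[bucket(r, dm, r0, inv_dr)] += 2.0;
      double dmp = dm;
      double dlast = std::fabs(y[i + m] - y[j + m]);
      if (dlast > dmp) dmp = dlast;
      if (dmp <= rmax) ainc[bucket(r, dmp, r0, inv_dr)] += 2.0;
    }
  }

  NumericMatrix out(2, nr);
  double bsum = 0.0, asum = 0.0;
  for (int k = 0; k < nr; ++k) {
    bsum += binc[k];
    asum += ainc[k];
    out(0, k) = bsum;
    out(1, k) = asum;
  }
  return out;
}

// Match counts for every embedding dimension m = 1..m_max in a single
// pair loop. Semantically identical to calling sampen_counts(y, m, r_abs)
// for each m; the running Chebyshev distance over a growing template can
// only increase, so a pair is abandoned as soon as it exceeds the largest
// tolerance.
//
// Returns a (2*m_max) x length(r_abs) matrix: rows (2m-1, 2m) = (B, A)
// for dimension m.
// [[Rcpp::export(name = ".sampen_counts_upto")]]
NumericMatrix sampen_counts_upto(NumericVector y, int m_max,
                                 NumericVector r_abs) {
  const int L = y.size();
  const int nr = r_abs.size();
  if (m_max < 1) stop("m_max must be >= 1");
  if (L - m_max < 1) stop("series too short: need length(y) - m_max >= 1");
  for (int k = 1; k < nr; ++k)
    if (r_abs[k] < r_abs[k - 1]) stop("r_abs must be sorted ascending");

  std::vector<double> r(r_abs.begin(), r_abs.end());
  const double r0 = nr ? r[0] : 0.0, inv_dr = grid_inv_step(r);
  const double rmax = nr ? r[nr - 1] : 0.0;
  // per-dimension first-bin increments, prefix-summed at the end
  std::vector<std::vector<double> > binc(m_max + 1,
                                         std::vector<double>(nr, 0.0));
  std::vector<std::vector<double> > ainc(m_max + 1,
                                         std::vector<double>(nr, 0.0));

  const int n1 = L - 1;  // m = 1 template count (widest range)
  for (int i = 0; i < n1 - 1; ++i) {
    for (int j = i + 1; j < n1; ++j) {
      double d = 0.0;
      // after element k (0-based) the distance covers k+1 elements:
      //   k+1 == m   -> B_m when j <= L-m-1, and A_{m-1} when m >= 2
      //   (A_{m-1}'s template range, starts <= L-m, always admits j here)
      const int kmax = std::min(m_max, L - 1 - j);
      for (int k = 0; k <= kmax; ++k) {
        double dk = std::fabs(y[i + k] - y[j + k]);
        if (dk > d) d = dk;
        if (d > rmax) break;
        const int len = k + 1;
        const int idx = bucket(r, d, r0, inv_dr);
        if (len <= m_max && j <= L - len - 1) binc[len][idx] += 2.0;
        if (len >= 2) ainc[len - 1][idx] += 2.0;
      }
    }
  }

  NumericMatrix out(2 * m_max, nr);
  for (int m = 1; m <= m_max; ++m) {
    double bsum = 0.0, asum = 0.0;
    for (int k = 0; k < nr; ++k) {
      bsum += binc[m][k];
      asum += ainc[m][k];
      out(2 * (m - 1), k) = bsum;
      out(2 * (m - 1) + 1, k) = asum;
    }
  }
  return out;
}

// Non-overlapping window averaging at scale tau; trailing remainder
// samples are discarded.
// [[Rcpp::export(name = ".coarse_grain_cpp")]]
NumericVector coarse_grain_cpp(NumericVector x, int tau) {
  const int N = x.size();
  if (tau < 1 || tau > N) stop("tau must satisfy 1 <= tau <= length(x)");
  const int L = N / tau;
  NumericVector y(L);
  for (int j = 0; j < L; ++j) {
    double s = 0.0;
    for (int i = 0; i < tau; ++i) s += x[j * tau + i];
    y[j] = s / tau;
  }
  return y;
}
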