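#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Pentadiagonal SPD solve of (diag(w) + lam * D2'D2) z = w .* y by banded
// Cholesky (bandwidth 2), where D2 is the second-difference operator on the
// index grid. O(n) per call.
static void whittaker_core(const double* y, const double* w, double lam,
                           int n, double* z) {
  std::vector<double> d0(n, 0.0), d1(n > 1 ? n - 1 : 0, 0.0), d2(n > 2 ? n - 2 : 0, 0.0);
  // accumulate D2'D2 bands from rows [1, -2, 1]
  for (int r = 0; r + 2 < n; ++r) {
    d0[r] += 1.0; d0[r + 1] += 4.0; d0[r + 2] += 1.0;
    d1[r] += -2.0; d1[r + 1] += -2.0;
    d2[r] += 1.0;
  }
  std::vector<double> m0(n), m1(n > 1 ? n - 1 : 0), m2(n > 2 ? n - 2 : 0);
  for (int i = 0; i < n; ++i) m0[i] = w[i] + lam * d0[i];
  for (int i = 0; i + 1 < n; ++i) m1[i] = lam * d1[i];
  for (int i = 0; i + 2 < n; ++i) m2[i] = lam * d2[i];
  // banded Cholesky M = L L'
  std::vector<double> l0(n), l1(n > 1 ? n - 1 : 0), l2(n > 2 ? n - 2 : 0);
  for (int i = 0; i < n; ++i) {
    double a = m0[i];
    if (i >= 1) a -= l1[i - 1] * l1[i - 1];
    if (i >= 2) a -= l2[i - 2] * l2[i - 2];
    l0[i] = std::sqrt(a);
    if (i + 1 < n) {
      double b = m1[i];
      if (i >= 1) b -= l1[i - 1] * l2[i - 1];
      l1[i] = b / l0[i];
    }
    if (i + 2 < n) l2[i] = m2[i] / l0[i];
  }
  // forward solve L u = w .* y
  std::vector<double> u(n);
  for (int i = 0; i < n; ++i) {
    double s = w[i] * y[i];
    if (i >= 1) s -= l1[i - 1] * u[i - 1];
    if (i >= 2) s -= l2[i - 2] * u[i - 2];
    u[i] = s / l0[i];
  }
  // back solve L' z = u
  for (int i = n - 1; i >= 0; --i) {
    double s = u[i];
    if (i + 1 < n) s -= l1[i] * z[i + 1];
    if (i + 2 < n) s -= l2[i] * z[i + 2];
    z[i] = s / l0[i];
  }
}

// [[Rcpp::export]]
NumericVector cpp_whittaker(NumericVector y, NumericVector w, double lam) {
  int n = y.size();
  NumericVector z(n);
  whittaker_core(REAL(y), REAL(w), lam, n, REAL(z));
  return z;
}

// Asymmetric least squares baseline: iterate the weighted Whittaker solve
// with w_i = p where y_i > z_i else 1-p, until the weight vector is stable
// (at most max_iter passes). Returns the baseline and iteration count.
// [[Rcpp::export]]
List cpp_asls(NumericVector y, double lam, double p, int max_iter) {
  int n = y.size();
  std::vector<double> w(n, 1.0);
  NumericVector z(n);
  int solves = 0;
  bool stable = false;
  for (int it = 0; it < max_iter; ++it) {
    whittaker_core(REAL(y), w.data(), lam, n, REAL(z));
    ++solves;
    bool changed = false;
    for (int i = 0; i < n; ++i) {
      double wi = (y[i] > z[i]) ? p : 1.0 - p;
      if (wi != w[i]) { w[i] = wi; changed = true; }
    }
    if (!changed) { stable = true; break; }
  }
  return List::create(_["baseline"] = z,
                      _["iterations"] = solves,
                      _["converged"] = stable);
}

// AsLS applied to every row of Y (pixels x channels). NA rows are passed
// through untouched (masked pixels).
// [[Rcpp::export]]
NumericMatrix cpp_asls_matrix(NumericMatrix Y, double lam, double p, int max_iter) {
  int nr = Y.nrow(), nc = Y.ncol();
  NumericMatrix Z(nr, nc);
  std::vector<double> y(nc), w(nc), z(nc);
  for (int r = 0; r < nr; ++r) {
    bool has_na = false;
    for (int c = 0; c < nc; ++c) {
      y[c] = Y(r, c);
      if (!std::isfinite(y[c])) has_na = true;
    }
    if (has_na) {
      for (int c = 0; c < nc; ++c) Z(r, c) = NA_REAL;
      continue;
    }
    std::fill(w.begin(), w.end(), 1.0);
    for (int it = 0; it < max_iter; ++it) {
      whittaker_core(y.data(), w.data(), lam, nc, z.data());
      bool changed = false;
      for (int c = 0; c < nc; ++c) {
        double wi = (y[c] > z[c]) ? p : 1.0 - p;
        if (wi != w[c]) { w[c] = wi; changed = true; }
      }
      if (!changed) break;
    }
    for (int c = 0; c < nc; ++c) Z(r, c) = z[c];
  }
  return Z;
}
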