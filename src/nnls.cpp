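#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Solve the k x k system G x = f restricted to the index set P by Gaussian
// elimination with partial pivoting. G is symmetric positive semi-definite
// (a Gram matrix); a tiny pivot signals rank deficiency and the affected
// coordinate is returned as 0.
static void solve_subset(const std::vector<double>& G, const std::vector<double>& f,
                         const std::vector<int>& P, int k, std::vector<double>& x) {
  int m = (int)P.size();
  std::vector<double> A(m * m), b(m);
  for (int i = 0; i < m; ++i) {
    b[i] = f[P[i]];
    for (int j = 0; j < m; ++j) A[i * m + j] = G[P[i] * k + P[j]];
  }
  std::vector<int> piv(m);
  for (int i = 0; i < m; ++i) piv[i] = i;
  for (int c = 0; c < m; ++c) {
    int best = c;
    double bv = std::fabs(A[piv[c] * m + c]);
    for (int r = c + 1; r < m; ++r) {
      double v = std::fabs(A[piv[r] * m + c]);
      if (v > bv) { bv = v; best = r; }
    }
    std::swap(piv[c], piv[best]);
    double d = A[piv[c] * m + c];
    if (std::fabs(d) < 1e-12) { A[piv[c] * m + c] = d = (d >= 0 ? 1e-12 : -1e-12); }
    for (int r = c + 1; r < m; ++r) {
      double fac = A[piv[r] * m + c] / d;
      if (fac == 0.0) continue;
      for (int cc = c; cc < m; ++cc) A[piv[r] * m + cc] -= fac * A[piv[c] * m + cc];
      b[piv[r]] -= fac * b[piv[c]];
    }
  }
  std::vector<double> y(m);
  for (int r = m - 1; r >= 0; --r) {
    double s = b[piv[r]];
    for (int c = r + 1; c < m; ++c) s -= A[piv[r] * m + c] * y[c];
    y[r] = s / A[piv[r] * m + r];
  }
  for (int i = 0; i < k; ++i) x[i] = 0.0;
  for (int i = 0; i < m; ++i) x[P[i]] = y[i];
}

// Lawson-Hanson NNLS on the normal equations: min ||A z - b|| s.t. z >= 0,
// given G = A'A and f = A'b. `allowed` restricts the support (equality-zero
// constraints for components declared absent).
static void nnls_normal(const std::vector<double>& G, const std::vector<double>& f,
                        int k, const std::vector<bool>& allowed, std::vector<double>& x) {
  std::vector<bool> inP(k, false);
  std::vector<int> P;
  std::vector<double> w(k), z(k);
  for (int i = 0; i < k; ++i) x[i] = 0.0;
  double fmax = 0.0;
  for (int i = 0; i < k; ++i) fmax = std::max(fmax, std::fabs(f[i]));
  const double tol = 1e-10 * (fmax > 0 ? fmax : 1.0);
  int outer = 0, outer_max = 30 * k + 30;
  while (outer++ < outer_max) {
    // gradient w = f - G x
    int best = -1; double bw = tol;
    for (int i = 0; i < k; ++i) {
      if (inP[i] || !allowed[i]) continue;
      double g = f[i];
      for (int j = 0; j < k; ++j) g -= G[i * k + j] * x[j];
      if (g > bw) { bw = g; best = i; }
    }
    if (best < 0) break;
    inP[best] = true;
    P.push_back(best);
    // inner loop: solve on P, backtrack while infeasible
    for (;;) {
      solve_subset(G, f, P, k, z);
      double alpha = 1.0; bool feasible = true;
      for (size_t ii = 0; ii < P.size(); ++ii) {
        int i = P[ii];
        if (z[i] <= 0) {
          feasible = false;
          double a = x[i] / (x[i] - z[i]);
          if (a < alpha) alpha = a;
        }
      }
      if (feasible) {
        for (int i = 0; i < k; ++i) x[i] = inP[i] ? z[i] : 0.0;
        break;
      }
      for (size_t ii = 0; ii < P.size(); ++ii) {
        int i = P[ii];
        x[i] += alpha * (z[i] - x[i]);
      }
      // drop coordinates that hit zero
      std::vector<int> keep;
      for (size_t ii = 0; ii < P.size(); ++ii) {
        int i = P[ii];
        if (x[i] > 1e-14) keep.push_back(i); else { x[i] = 0.0; inP[i] = false; }
      }
      P = keep;
      if (P.empty()) break;
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_nnls(NumericMatrix A, NumericVector b) {
  int m = A.nrow(), k = A.ncol();
  std::vector<double> G(k * k, 0.0), f(k, 0.0);
  for (int i = 0; i < k; ++i) {
    for (int j = i; j < k; ++j) {
      double s = 0.0;
      for (int r = 0; r < m; ++r) s += A(r, i) * A(r, j);
      G[i * k + j] = G[j * k + i] = s;
    }
    double s = 0.0;
    for (int r = 0; r < m; ++r) s += A(r, i) * b[r];
    f[i] = s;
  }
  std::vector<bool> allowed(k, true);
  std::vector<double> x(k);
  nnls_normal(G, f, k, allowed, x);
  return NumericVector(x.begin(), x.end());
}

// Batched NNLS on normal equations: G is the k x k Gram matrix shared by
// all problems, F holds one projection vector A'b per row. Row r's support
// is restricted to the components allowed for its block (presence row
// block_of[r], 0-based). The Gram/projection products are computed in R via
// BLAS; this loop only runs the active-set solves.
// [[Rcpp::export]]
NumericMatrix cpp_nnls_batch(NumericMatrix Gm, NumericMatrix F,
                             IntegerVector block_of, LogicalMatrix presence) {
  int k = Gm.ncol(), n = F.nrow();
  std::vector<double> G(k * k);
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j) G[i * k + j] = Gm(i, j);
  NumericMatrix X(n, k);
  std::vector<double> f(k), x(k);
  std::vector<bool> allowed(k);
  for (int r = 0; r < n; ++r) {
    int bl = block_of[r];
    for (int i = 0; i < k; ++i) {
      allowed[i] = presence(bl, i);
      f[i] = F(r, i);
    }
    nnls_normal(G, f, k, allowed, x);
    for (int i = 0; i < k; ++i) X(r, i) = x[i];
  }
  return X;
}
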