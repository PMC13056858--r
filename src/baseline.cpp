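#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Solve (W + lambda * D2' D2) z = W y for the Whittaker smoother with
// second-order differences, where W = diag(w).  The system matrix is
// symmetric positive definite and pentadiagonal; we factor it with a
// banded LDL^T (bandwidth 2), O(n) time and memory.
static void whittaker_solve(const NumericVector& y, const NumericVector& w,
                            double lambda, NumericVector& z) {
  const int n = y.size();
  if (n < 3) { for (int i = 0; i < n; ++i) z[i] = y[i]; return; }

  std::vector<double> d0(n), d1(n, 0.0), d2(n, 0.0);
  // band of lambda * D2'D2
  for (int i = 0; i < n; ++i) {
    double diag;
    if (i == 0 || i == n - 1)      diag = 1.0;
    else if (i == 1 || i == n - 2) diag = 5.0;
    else                           diag = 6.0;
    if (n == 3 && i == 1) diag = 4.0;  // single difference row
    d0[i] = w[i] + lambda * diag;
  }
  for (int i = 0; i + 1 < n; ++i) {
    double off = (i == 0 || i == n - 2) ? -2.0 : -4.0;
    d1[i] = lambda * off;
  }
  for (int i = 0; i + 2 < n; ++i) d2[i] = lambda * 1.0;

  // banded LDL^T: A = L D L^T with unit lower-triangular L (bands l1, l2)
  std::vector<double> D(n), l1(n, 0.0), l2(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double di = d0[i];
    if (i >= 1) di -= l1[i - 1] * l1[i - 1] * D[i - 1];
    if (i >= 2) di -= l2[i - 2] * l2[i - 2] * D[i - 2];
    D[i] = di;
    if (i + 1 < n) {
      double e = d1[i];
      if (i >= 1) e -= l1[i - 1] * l2[i - 1] * D[i - 1];
      l1[i] = e / D[i];
    }
    if (i + 2 < n) l2[i] = d2[i] / D[i];
  }
  // forward solve L v = W y
  std::vector<double> v(n);
  for (int i = 0; i < n; ++i) {
    double b = w[i] * y[i];
    if (i >= 1) b -= l1[i - 1] * v[i - 1];
    if (i >= 2) b -= l2[i - 2] * v[i - 2];
    v[i] = b;
  }
  // back solve D L^T z = v
  for (int i = n - 1; i >= 0; --i) {
    double x = v[i] / D[i];
    if (i + 1 < n) x -= l1[i] * z[i + 1];
    if (i + 2 < n) x -= l2[i] * z[i + 2];
    z[i] = x;
  }
}

// [[Rcpp::export]]
NumericVector whittaker_smooth_cpp(NumericVector y, NumericVector w, double lambda) {
  NumericVector z(y.size());
  whittaker_solve(y, w, lambda, z);
  return z;
}

// Adaptive iterative reweighted penalized least squares (airPLS-style).
// Points above the running baseline estimate are progressively removed
// from the fit; weights for points below decay exponentially with the
// iteration index so isolated dips do not drag the baseline down.
// [[Rcpp::export]]
List airpls_cpp(NumericVector y, double lambda, int max_iter, double tol) {
  const int n = y.size();
  NumericVector w(n, 1.0), z(n);
  double ytot = 0.0;
  for (int i = 0; i < n; ++i) ytot += std::fabs(y[i]);
  bool converged = false;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    whittaker_solve(y, w, lambda, z);
    double s = 0.0, dmax = 0.0;
    for (int i = 0; i < n; ++i) {
      double d = y[i] - z[i];
      if (d < 0.0) { s += -d; if (-d > dmax) dmax = -d; }
    }
    if (s < tol * ytot || ytot == 0.0) { converged = true; break; }
    for (int i = 0; i < n; ++i) {
      double d = y[i] - z[i];
      w[i] = (d >= 0.0) ? 0.0 : std::exp((double)iter * (-d) / s);
    }
    // keep the spectrum ends anchored so the baseline cannot fly off
    w[0] = std::exp((double)iter * dmax / s);
    w[n - 1] = w[0];
  }
  if (iter > max_iter) iter = max_iter;
  return List::create(_["baseline"] = z,
                      _["iterations"] = iter,
                      _["converged"] = converged);
}

// Half-height support bounds for candidate peak apexes.  From each apex,
// extend left/right while the signal stays at or above half the apex
// height and keeps descending; stop at the first rise (valley between
// overlapping peaks) or when the signal drops below half height.
// Returns an (n_apex x 2) matrix of 1-based [left, right] indices.
// [[Rcpp::export]]
IntegerMatrix peak_support_cpp(NumericVector y, IntegerVector apex) {
  const int n = y.size(), m = apex.size();
  IntegerMatrix out(m, 2);
  for (int k = 0; k < m; ++k) {
    int a = apex[k] - 1;
    double half = 0.5 * y[a];
    int L = a, R = a;
    while (L > 0 && y[L - 1] >= half && y[L - 1] <= y[L]) --L;
    while (R < n - 1 && y[R + 1] >= half && y[R + 1] <= y[R]) ++R;
    out(k, 0) = L + 1;
    out(k, 1) = R + 1;
  }
  return out;
}
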