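#include <Rcpp.h>
using namespace Rcpp;

// Cascade of biquad sections in direct-form II transposed.
// sos: n_sections x 6 matrix, rows (b0, b1, b2, a0, a1, a2) with a0 == 1.
// [[Rcpp::export]]
NumericVector sosfilt_cpp(NumericMatrix sos, NumericVector x) {
  const int ns = sos.nrow();
  const R_xlen_t n = x.size();
  NumericVector y = clone(x);
  for (int s = 0; s < ns; ++s) {
    const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    const double a1 = sos(s, 4), a2 = sos(s, 5);
    double z1 = 0.0, z2 = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) {
      const double xn = y[i];
      const double yn = b0 * xn + z1;
      z1 = b1 * xn - a1 * yn + z2;
      z2 = b2 * xn - a2 * yn;
      y[i] = yn;
    }
  }
  return y;
}

// Linear SVM via dual coordinate descent on the L1 (hinge) loss,
// L2-regularised primal  min_w 0.5 |w|^2 + C sum_i max(0, 1 - y_i w.x_i).
// X: n x d (bias handled by the caller through an appended constant column);
// y in {-1, +1}. Rows are visited in the fixed order given, so the caller
// shuffles once under its own seed and the solve stays deterministic.
// [[Rcpp::export]]
List svm_dcd_cpp(NumericMatrix X, NumericVector y, double C,
                 int max_pass, double tol) {
  const int n = X.nrow(), d = X.ncol();
  NumericVector w(d), alpha(n), qii(n);
  for (int i = 0; i < n; ++i) {
    double q = 0.0;
    for (int j = 0; j < d; ++j) q += X(i, j) * X(i, j);
    qii[i] = q;
  }
  int pass = 0;
  bool converged = false;
  for (; pass < max_pass; ++pass) {
    double max_pg = 0.0;
    for (int i = 0; i < n; ++i) {
      if (qii[i] <= 0.0) continue;
      double wx = 0.0;
      for (int j = 0; j < d; ++j) wx += w[j] * X(i, j);
      const double G = y[i] * wx - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0) PG = G < 0.0 ? G : 0.0;
      else if (alpha[i] >= C) PG = G > 0.0 ? G : 0.0;
      if (std::abs(PG) > max_pg) max_pg = std::abs(PG);
      if (std::abs(PG) > 1e-12) {
        const double a_old = alpha[i];
        double a = a_old - G / qii[i];
        if (a < 0.0) a = 0.0; else if (a > C) a = C;
        alpha[i] = a;
        const double delta = (a - a_old) * y[i];
        if (delta != 0.0)
          for (int j = 0; j < d; ++j) w[j] += delta * X(i, j);
      }
    }
    if (max_pg < tol) { converged = true; ++pass; break; }
  }
  return List::create(_["w"] = w, _["alpha"] = alpha,
                      _["passes"] = pass, _["converged"] = converged);
}
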