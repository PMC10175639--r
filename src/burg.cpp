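#include <Rcpp.h>
using namespace Rcpp;

// Burg (maximum-entropy) autoregressive coefficients of fixed order for each
// column of `x` (columns already mean-removed). Returns an order x ncol
// matrix with the convention x_t = sum_k a_k x_{t-k} + e_t (the sign used by
// stats::ar.burg$ar). A column whose reflection-coefficient denominator
// vanishes (constant/zero column) gets all-NA coefficients.
// [[Rcpp::export(name = ".burg_coef")]]
NumericMatrix burg_coef(NumericMatrix x, int order) {
  int n = x.nrow(), nc = x.ncol();
  NumericMatrix out(order, nc);
  std::vector<double> f(n), b(n), a(order), tmp(order);
  for (int c = 0; c < nc; ++c) {
    for (int t = 0; t < n; ++t) f[t] = b[t] = x(t, c);
    bool ok = true;
    std::fill(a.begin(), a.end(), 0.0);
    for (int m = 0; m < order; ++m) {
      double num = 0.0, den = 0.0;
      for (int t = m + 1; t < n; ++t) {
        num += f[t] * b[t - 1];
        den += f[t] * f[t] + b[t - 1] * b[t - 1];
      }
      if (den <= 0.0) { ok = false; break; }
      double k = 2.0 * num / den;
      for (int i = 0; i < m; ++i) tmp[i] = a[i] - k * a[m - 1 - i];
      for (int i = 0; i < m; ++i) a[i] = tmp[i];
      a[m] = k;
      for (int t = n - 1; t > m; --t) {
        double ft = f[t];
        f[t] = ft - k * b[t - 1];
        b[t] = b[t - 1] - k * ft;
      }
    }
    for (int i = 0; i < order; ++i) {
      out(i, c) = ok ? a[i] : NA_REAL;
    }
  }
  return out;
}
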