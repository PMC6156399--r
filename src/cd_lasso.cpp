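#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for min ||D w - x||_2^2 + lam * ||w||_1,
// optionally with w >= 0. Exact soft-threshold updates; deterministic.
// [[Rcpp::export(name = ".cd_lasso")]]
NumericVector cd_lasso(NumericVector x, NumericMatrix D, double lam,
                       bool nonneg, double tol, int max_iter) {
  const int n = D.nrow(), p = D.ncol();
  NumericVector w(p), dd(p);
  std::vector<double> r(x.begin(), x.end());   // residual x - D w
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += D(i, j) * D(i, j);
    dd[j] = s;
  }
  const double half = lam / 2.0;
  for (int iter = 0; iter < max_iter; ++iter) {
    double delta = 0.0;
    for (int j = 0; j < p; ++j) {
      if (dd[j] == 0.0) continue;
      double z = dd[j] * w[j];
      for (int i = 0; i < n; ++i) z += D(i, j) * r[i];
      double wj;
      if (nonneg) {
        wj = z - half;
        if (wj < 0.0) wj = 0.0;
        wj /= dd[j];
      } else {
        double a = std::fabs(z) - half;
        wj = (a > 0.0) ? ((z > 0.0 ? a : -a) / dd[j]) : 0.0;
      }
      if (wj != w[j]) {
        const double diff = wj - w[j];
        for (int i = 0; i < n; ++i) r[i] -= D(i, j) * diff;
        if (std::fabs(diff) > delta) delta = std::fabs(diff);
        w[j] = wj;
      }
    }
    if (delta < tol) break;
  }
  return w;
}
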