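#include <Rcpp.h>
using namespace Rcpp;

// Fused in-place Adam update: p -= lr * (m/bc1) / (sqrt(v/bc2) + eps)
// with m, v updated in place.  All four vectors must be un-aliased R
// numerics owned by the optimizer (the R side copies on snapshot).
// [[Rcpp::export]]
void adam_update_inplace(NumericVector p, NumericVector g,
                         NumericVector m, NumericVector v,
                         double lr, double beta1, double beta2,
                         double eps, double bc1, double bc2) {
  R_xlen_t n = p.size();
  if (g.size() != n || m.size() != n || v.size() != n)
    stop("adam_update_inplace: length mismatch");
  double *pp = REAL(p), *pg = REAL(g), *pm = REAL(m), *pv = REAL(v);
  const double om1 = 1.0 - beta1, om2 = 1.0 - beta2;
  const double inv1 = 1.0 / bc1, inv2 = 1.0 / bc2;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = pg[i];
    const double mi = beta1 * pm[i] + om1 * gi;
    const double vi = beta2 * pv[i] + om2 * gi * gi;
    pm[i] = mi;
    pv[i] = vi;
    pp[i] -= lr * (mi * inv1) / (std::sqrt(vi * inv2) + eps);
  }
}
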