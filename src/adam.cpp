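#include <Rcpp.h>
#include <cmath>

// In-place Adam update for one parameter array. param, m and v are
// modified in place; the caller owns unshared copies (train_model
// duplicates parameters at the start of training).
// [[Rcpp::export(rng = false)]]
void adam_update_(Rcpp::NumericVector param, Rcpp::NumericVector m,
                  Rcpp::NumericVector v, Rcpp::NumericVector grad,
                  double corr, double b1, double b2, double eps) {
  const R_xlen_t n = param.size();
  if (m.size() != n || v.size() != n || grad.size() != n)
    Rcpp::stop("adam_update_: length mismatch");
  double *p = param.begin(), *mm = m.begin(), *vv = v.begin(),
         *g = grad.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = g[i];
    mm[i] = b1 * mm[i] + (1.0 - b1) * gi;
    vv[i] = b2 * vv[i] + (1.0 - b2) * gi * gi;
    p[i] -= corr * mm[i] / (std::sqrt(vv[i]) + eps);
  }
}
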