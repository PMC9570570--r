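#include <Rcpp.h>
using namespace Rcpp;

// In-place Adam updates for one parameter block. The caller owns the
// aliasing discipline: W, m and v must be private to the running
// optimizer (freshly allocated at training start).

static inline void adam_block(double *w, double *m, double *v,
                              const double *g, R_xlen_t n, double lr,
                              double b1, double b2, double eps,
                              double scale, double bc1, double bc2) {
  for (R_xlen_t i = 0; i < n; ++i) {
    double gi = g[i] * scale;
    m[i] = b1 * m[i] + (1.0 - b1) * gi;
    v[i] = b2 * v[i] + (1.0 - b2) * gi * gi;
    w[i] -= lr * (m[i] / bc1) / (std::sqrt(v[i] / bc2) + eps);
  }
}

// [[Rcpp::export(name = ".sgd_update")]]
void sgd_update(NumericVector W, NumericVector g, double lr, double scale) {
  double *w = REAL(W);
  const double *gp = REAL(g);
  R_xlen_t n = W.size();
  for (R_xlen_t i = 0; i < n; ++i) w[i] -= lr * scale * gp[i];
}

// [[Rcpp::export(name = ".adam_update")]]
void adam_update(NumericVector W, NumericVector m, NumericVector v,
                 NumericVector g, double lr, double b1, double b2,
                 double eps, double scale, int t) {
  double bc1 = 1.0 - std::pow(b1, t);
  double bc2 = 1.0 - std::pow(b2, t);
  adam_block(REAL(W), REAL(m), REAL(v), REAL(g), W.size(), lr, b1, b2,
             eps, scale, bc1, bc2);
}
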