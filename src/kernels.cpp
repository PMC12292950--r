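// Fused elementwise kernels for the training loops. Matrix products go
// through R's BLAS; these kernels collapse the activation arithmetic into
// single passes to cut allocation traffic on the large collocation matrices.
#include <Rcpp.h>
using namespace Rcpp;

// swish(Z + bias) with bias applied per column; returns the activation and
// the quantities the backward pass needs
// [[Rcpp::export(name = ".swish_fwd")]]
List swish_fwd(NumericMatrix z, NumericVector bias) {
  R_xlen_t nr = z.nrow(), nc = z.ncol();
  NumericMatrix out(nr, nc), zb(nr, nc), s(nr, nc);
  for (R_xlen_t j = 0; j < nc; ++j) {
    double bj = bias[j];
    const double* zc = &z(0, j);
    double* oc = &out(0, j);
    double* zbc = &zb(0, j);
    double* sc = &s(0, j);
    for (R_xlen_t i = 0; i < nr; ++i) {
      double v = zc[i] + bj;
      double sig = 1.0 / (1.0 + std::exp(-v));
      zbc[i] = v;
      sc[i] = sig;
      oc[i] = v * sig;
    }
  }
  return List::create(out, zb, s);
}

// gradient through swish: g * (s + z * s * (1 - s))
// [[Rcpp::export(name = ".swish_bwd")]]
NumericMatrix swish_bwd(NumericMatrix g, NumericMatrix zb, NumericMatrix s) {
  R_xlen_t n = g.size();
  NumericMatrix gz(g.nrow(), g.ncol());
  const double* gp = g.begin();
  const double* zp = zb.begin();
  const double* sp = s.begin();
  double* op = gz.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    double sv = sp[i];
    op[i] = gp[i] * (sv + zp[i] * sv * (1.0 - sv));
  }
  return gz;
}

// softplus and its sigmoid factor in one pass
// [[Rcpp::export(name = ".softplus_fwd")]]
List softplus_fwd(NumericMatrix x) {
  R_xlen_t n = x.size();
  NumericMatrix out(x.nrow(), x.ncol()), s(x.nrow(), x.ncol());
  const double* xp = x.begin();
  double* op = out.begin();
  double* sp = s.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = xp[i];
    if (v > 30.0) {
      op[i] = v;
      sp[i] = 1.0;
    } else {
      double e = std::exp(v);
      op[i] = std::log1p(e);
      sp[i] = e / (1.0 + e);
    }
  }
  return List::create(out, s);
}
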