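#include <Rcpp.h>
using namespace Rcpp;

// Fused Adam step for a complex parameter array whose real and imaginary
// parts are independent real parameters. `g` carries dL/d(conj p), so the
// real-parameter gradients are 2*Re(g) and 2*Im(g); `m` and `v` pack the
// first and second moments of the two real parameters into one complex
// array. Returns list(param, m, v).
// [[Rcpp::export]]
List adam_step_complex(ComplexVector param, ComplexVector m, ComplexVector v,
                       ComplexVector g, double lr, double b1, double b2,
                       double eps, int t, double gscale = 1.0) {
  R_xlen_t n = param.size();
  ComplexVector p2(n), m2(n), v2(n);
  double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
  for (R_xlen_t i = 0; i < n; ++i) {
    double gr = 2.0 * gscale * g[i].r, gi = 2.0 * gscale * g[i].i;
    double mr = b1 * m[i].r + (1 - b1) * gr;
    double mi = b1 * m[i].i + (1 - b1) * gi;
    double vr = b2 * v[i].r + (1 - b2) * gr * gr;
    double vi = b2 * v[i].i + (1 - b2) * gi * gi;
    m2[i].r = mr; m2[i].i = mi;
    v2[i].r = vr; v2[i].i = vi;
    p2[i].r = param[i].r - lr * (mr / c1) / (std::sqrt(vr / c2) + eps);
    p2[i].i = param[i].i - lr * (mi / c1) / (std::sqrt(vi / c2) + eps);
  }
  return List::create(_["param"] = p2, _["m"] = m2, _["v"] = v2);
}
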