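#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Orientationally averaged Debye double sum for one fixed bead-model
// conformation.  Within one sub-unit the average runs over distinct bead
// pairs only (the i = j diagonal is a discretization artifact of relative
// weight 1/n_beads, not part of the continuous body's form factor), which
// makes the estimator unbiased for rigid bodies sampled as iid point
// clouds.  `unit` gives each bead's sub-unit index (0-based); `mult` the
// per-unit within-pair reweighting n/(n-1).
// [[Rcpp::export]]
NumericVector debye_sum_cpp(NumericMatrix X, NumericVector w,
                            IntegerVector unit, NumericVector mult,
                            NumericVector q) {
  const int n = X.nrow(), nq = q.size();
  NumericVector out(nq);
  const double *x = &X(0, 0), *y = &X(0, 1), *z = &X(0, 2);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double ww = 2.0 * w[i] * w[j];
      if (unit[i] == unit[j]) ww *= mult[unit[i]];
      for (int iq = 0; iq < nq; ++iq) {
        const double t = q[iq] * r;
        out[iq] += ww * (t < 1e-9 ? 1.0 : std::sin(t) / t);
      }
    }
  }
  return out;
}
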