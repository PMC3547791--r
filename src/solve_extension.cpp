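#include <Rcpp.h>
using namespace Rcpp;

// Marko-Siggia interpolation force at fractional extension z = x/Lc,
// in units of kBT/p.
static inline double msForce(double z) {
  double o = 1.0 - z;
  return 0.25 / (o * o) - 0.25 + z;
}

// Solve the force balance k * (X - x - rise) = F_wlc(x; Lc, p, T) for the
// chain extension x at each spring-end position X.  The WLC restoring force
// is strictly increasing in x, so the balance has a unique root in
// [0, Lc).  Bisection to ~1e-10 A.
// [[Rcpp::export(name = ".solveExtensionCpp")]]
NumericVector solveExtension(NumericVector X, double Lc, double rise,
                             double k, double kT, double p) {
  const int n = X.size();
  const double kTp = kT / p;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double avail = X[i] - rise;   // spring-end position relative to the
    if (avail <= 0.0) {           // folded core; slack chain -> x = 0
      out[i] = 0.0;
      continue;
    }
    double lo = 0.0, hi = std::min(avail, 0.999999 * Lc);
    // f(lo) = k*avail >= 0, f(hi) <= 0 unless chain cannot reach balance
    for (int it = 0; it < 80; ++it) {
      double mid = 0.5 * (lo + hi);
      double f = k * (avail - mid) - kTp * msForce(mid / Lc);
      if (f > 0.0) lo = mid; else hi = mid;
      if (hi - lo < 1e-10) break;
    }
    out[i] = 0.5 * (lo + hi);
  }
  return out;
}
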