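#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Direct-form II transposed IIR filter with initial conditions.
// b, a must have equal length with a[0] == 1 (normalise upstream);
// zi has length(b) - 1. With reverse = true the sequence is filtered
// back-to-front and the output re-reversed, so both passes of a
// zero-phase filter avoid R-level copies. Returns the filtered signal
// and final state.
// [[Rcpp::export]]
List lfilter_state(NumericVector b, NumericVector a, NumericVector x,
                   NumericVector zi, bool reverse = false) {
  const int n = x.size();
  const int nf = b.size();
  if (a.size() != nf) stop("b and a must have equal length");
  if (zi.size() != nf - 1) stop("zi must have length(b) - 1");
  std::vector<double> bb(b.begin(), b.end());
  std::vector<double> aa(a.begin(), a.end());
  std::vector<double> z(zi.begin(), zi.end());
  NumericVector y(n);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  const int start = reverse ? n - 1 : 0;
  const int step = reverse ? -1 : 1;
  const double b0 = bb[0];
  if (nf == 5) {            // the common band-pass case, kept in registers
    const double b1 = bb[1], b2 = bb[2], b3 = bb[3], b4 = bb[4];
    const double a1 = aa[1], a2 = aa[2], a3 = aa[3], a4 = aa[4];
    double z0 = z[0], z1 = z[1], z2 = z[2], z3 = z[3];
    for (int k = 0, i = start; k < n; ++k, i += step) {
      const double xi = xp[i];
      const double yi = b0 * xi + z0;
      z0 = b1 * xi + z1 - a1 * yi;
      z1 = b2 * xi + z2 - a2 * yi;
      z2 = b3 * xi + z3 - a3 * yi;
      z3 = b4 * xi - a4 * yi;
      yp[i] = yi;
    }
    z[0] = z0; z[1] = z1; z[2] = z2; z[3] = z3;
  } else {
    for (int k = 0, i = start; k < n; ++k, i += step) {
      const double xi = xp[i];
      const double yi = b0 * xi + z[0];
      for (int j = 0; j < nf - 2; ++j)
        z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
      z[nf - 2] = bb[nf - 1] * xi - aa[nf - 1] * yi;
      yp[i] = yi;
    }
  }
  return List::create(_["y"] = y,
                      _["zf"] = NumericVector(z.begin(), z.end()));
}
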