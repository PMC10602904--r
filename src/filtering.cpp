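#include <Rcpp.h>
using namespace Rcpp;

// One biquad pass, direct form II transposed. Coefficients normalised so
// a0 == 1.
static void biquad_forward(std::vector<double>& x, const double* b,
                           const double* a) {
  double z1 = 0.0, z2 = 0.0;
  const double b0 = b[0], b1 = b[1], b2 = b[2], a1 = a[1], a2 = a[2];
  for (size_t i = 0; i < x.size(); ++i) {
    const double xi = x[i];
    const double yi = b0 * xi + z1;
    z1 = b1 * xi - a1 * yi + z2;
    z2 = b2 * xi - a2 * yi;
    x[i] = yi;
  }
}

// Zero-phase (forward-backward) filtering through a cascade of biquad
// sections with odd-reflection padding at both ends. `sections` is an
// n_sections x 6 matrix of (b0, b1, b2, a0, a1, a2) rows with a0 == 1.
// [[Rcpp::export(name = ".sos_filtfilt")]]
NumericVector sos_filtfilt(NumericMatrix sections, NumericVector x,
                           int pad) {
  const int n = x.size();
  if (n < 4) stop("signal too short to filter");
  if (pad > n - 1) pad = n - 1;
  if (pad < 0) pad = 0;
  std::vector<double> xp(n + 2 * pad);
  for (int i = 0; i < pad; ++i) xp[i] = 2.0 * x[0] - x[pad - i];
  for (int i = 0; i < n; ++i) xp[pad + i] = x[i];
  for (int i = 0; i < pad; ++i) xp[pad + n + i] = 2.0 * x[n - 1] - x[n - 2 - i];
  const int ns = sections.nrow();
  for (int s = 0; s < ns; ++s) {
    double b[3] = {sections(s, 0), sections(s, 1), sections(s, 2)};
    double a[3] = {sections(s, 3), sections(s, 4), sections(s, 5)};
    biquad_forward(xp, b, a);
    std::reverse(xp.begin(), xp.end());
    biquad_forward(xp, b, a);
    std::reverse(xp.begin(), xp.end());
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = xp[pad + i];
  return out;
}
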