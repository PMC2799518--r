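#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Ligand-receptor trafficking network, mass-action form.
// Species order (columns): L, R1, R2, LRCP, LRCE, R1E, R2E.
// Reactions:
//   L + R1 + R2 -> LRCP            (k_bind, trimolecular)
//   LRCP -> LRCE                   (k_int_complex)
//   R1 -> R1E, R2 -> R2E           (k_int_receptor, constitutive)
//   R1E -> R1, R2E -> R2           (k_recycle)
//   LRCP -> 0, LRCE -> 0           (k_deg_complex)
//   R1E -> 0, R2E -> 0             (k_deg_receptor)
//   0 -> R1, 0 -> R2               (prod_r1, prod_r2)
// With all degradation and production rates zero, R1 + R1E + LRCP + LRCE and
// R2 + R2E + LRCP + LRCE are conserved.

static inline void deriv(const double *y, double *dy, const double *p) {
  const double ka = p[0], kic = p[1], kir = p[2], kr = p[3];
  const double kdc = p[4], kdr = p[5], p1 = p[6], p2 = p[7];
  const double vb = ka * y[0] * y[1] * y[2];
  dy[0] = -vb;
  dy[1] = p1 - vb - kir * y[1] + kr * y[5];
  dy[2] = p2 - vb - kir * y[2] + kr * y[6];
  dy[3] = vb - (kic + kdc) * y[3];
  dy[4] = kic * y[3] - kdc * y[4];
  dy[5] = kir * y[1] - (kr + kdr) * y[5];
  dy[6] = kir * y[2] - (kr + kdr) * y[6];
}

// Cash-Karp embedded Runge-Kutta 4(5) coefficients.
static const double B21 = 1.0 / 5.0;
static const double B31 = 3.0 / 40.0, B32 = 9.0 / 40.0;
static const double B41 = 3.0 / 10.0, B42 = -9.0 / 10.0, B43 = 6.0 / 5.0;
static const double B51 = -11.0 / 54.0, B52 = 5.0 / 2.0, B53 = -70.0 / 27.0,
                    B54 = 35.0 / 27.0;
static const double B61 = 1631.0 / 55296.0, B62 = 175.0 / 512.0,
                    B63 = 575.0 / 13824.0, B64 = 44275.0 / 110592.0,
                    B65 = 253.0 / 4096.0;
static const double C1 = 37.0 / 378.0, C3 = 250.0 / 621.0, C4 = 125.0 / 594.0,
                    C6 = 512.0 / 1771.0;
static const double D1 = 2825.0 / 27648.0, D3 = 18575.0 / 48384.0,
                    D4 = 13525.0 / 55296.0, D5 = 277.0 / 14336.0, D6 = 1.0 / 4.0;

#define NS 7

// Advance one state vector from t = 0 to t = dt with adaptive step control.
static void integrate_one(double *y, const double *p, double dt,
                          double rtol, double atol) {
  double t = 0.0, h = dt / 100.0;
  double k1[NS], k2[NS], k3[NS], k4[NS], k5[NS], k6[NS];
  double ytmp[NS], yout[NS], yerr[NS];
  int guard = 0;
  while (t < dt && ++guard < 1000000) {
    if (t + h > dt) h = dt - t;
    deriv(y, k1, p);
    for (int i = 0; i < NS; i++) ytmp[i] = y[i] + h * B21 * k1[i];
    deriv(ytmp, k2, p);
    for (int i = 0; i < NS; i++) ytmp[i] = y[i] + h * (B31 * k1[i] + B32 * k2[i]);
    deriv(ytmp, k3, p);
    for (int i = 0; i < NS; i++)
      ytmp[i] = y[i] + h * (B41 * k1[i] + B42 * k2[i] + B43 * k3[i]);
    deriv(ytmp, k4, p);
    for (int i = 0; i < NS; i++)
      ytmp[i] = y[i] + h * (B51 * k1[i] + B52 * k2[i] + B53 * k3[i] + B54 * k4[i]);
    deriv(ytmp, k5, p);
    for (int i = 0; i < NS; i++)
      ytmp[i] = y[i] + h * (B61 * k1[i] + B62 * k2[i] + B63 * k3[i] +
                            B64 * k4[i] + B65 * k5[i]);
    deriv(ytmp, k6, p);
    double errmax = 0.0;
    for (int i = 0; i < NS; i++) {
      yout[i] = y[i] + h * (C1 * k1[i] + C3 * k3[i] + C4 * k4[i] + C6 * k6[i]);
      double y5 = y[i] + h * (D1 * k1[i] + D3 * k3[i] + D4 * k4[i] +
                              D5 * k5[i] + D6 * k6[i]);
      yerr[i] = yout[i] - y5;
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(yout[i]));
      double e = std::fabs(yerr[i]) / sc;
      if (e > errmax) errmax = e;
    }
    // positivity guard: concentrations cannot undershoot zero; reject the
    // step and refine instead of clipping (exact zeros are admitted once the
    // step is already tiny, where the undershoot is below atol)
    bool neg = false;
    for (int i = 0; i < NS; i++) if (yout[i] < 0.0) neg = true;
    if (neg && h > 1e-8) {
      h *= 0.5;
      continue;
    }
    if (errmax <= 1.0) {
      t += h;
      for (int i = 0; i < NS; i++) y[i] = (neg && yout[i] < 0.0) ? 0.0 : yout[i];
      double fac = (errmax > 1e-12) ? 0.9 * std::pow(errmax, -0.2) : 5.0;
      if (fac > 5.0) fac = 5.0;
      h *= fac;
    } else {
      double fac = 0.9 * std::pow(errmax, -0.25);
      if (fac < 0.1) fac = 0.1;
      h *= fac;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix trafficking_cpp(NumericMatrix state, NumericVector params,
                              double dt, double rtol, double atol) {
  if (state.ncol() != NS) stop("trafficking_cpp: state must have 7 columns");
  if (params.size() != 8) stop("trafficking_cpp: 8 rate parameters expected");
  const int n = state.nrow();
  NumericMatrix out(clone(state));
  double p[8];
  for (int i = 0; i < 8; i++) p[i] = params[i];
  double y[NS];
  for (int r = 0; r < n; r++) {
    for (int i = 0; i < NS; i++) y[i] = out(r, i);
    integrate_one(y, p, dt, rtol, atol);
    for (int i = 0; i < NS; i++) out(r, i) = y[i];
  }
  return out;
}

// [[Rcpp::export]]
String fnv1a64_cpp(IntegerVector bytes) {
  uint64_t hash = 1469598103934665603ULL;
  const uint64_t prime = 1099511628211ULL;
  for (int i = 0; i < bytes.size(); i++) {
    hash ^= (uint64_t)(bytes[i] & 0xff);
    hash *= prime;
  }
  char buf[17];
  snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)hash);
  return String(buf);
}
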