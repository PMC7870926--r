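#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Mass-action RHS. par = (alpha_p, beta_p, alpha_S, beta_Sp, kon_cell,
// koff, kcat); kon_cell already converted to (copies/cell)^-1 s^-1.
static inline void rhs(const double* par, const double* y, double* dy) {
  const double bind = par[4] * y[1] * y[0];
  const double unbind = par[5] * y[2];
  dy[0] = par[0] - par[1] * y[0] - bind + unbind;
  dy[1] = par[2] - par[3] * y[1] - bind + unbind;
  dy[2] = bind - unbind - par[6] * y[2];
}

// Adaptive Dormand-Prince 5(4) integration of the three-species model,
// evaluated exactly at the requested output times. Error control uses the
// embedded 4th-order solution with mixed absolute/relative tolerance.
// [[Rcpp::export]]
NumericMatrix kinetics_dopri(NumericVector par, NumericVector y0,
                             NumericVector times, double rtol = 1e-8,
                             double atol = 1e-10) {
  // Dormand-Prince coefficients
  static const double
    a21 = 1.0 / 5,
    a31 = 3.0 / 40, a32 = 9.0 / 40,
    a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9,
    a51 = 19372.0 / 6561, a52 = -25360.0 / 2187, a53 = 64448.0 / 6561,
    a54 = -212.0 / 729,
    a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
    a64 = 49.0 / 176, a65 = -5103.0 / 18656,
    b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
    b5 = -2187.0 / 6784, b6 = 11.0 / 84,
    e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
    e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

  const int nt = times.size();
  NumericMatrix out(nt, 3);
  double y[3] = { y0[0], y0[1], y0[2] };
  double t = times[0];
  out(0, 0) = y[0]; out(0, 1) = y[1]; out(0, 2) = y[2];

  const double* p = par.begin();
  double k1[3], k2[3], k3[3], k4[3], k5[3], k6[3], k7[3], yt[3], ynew[3];
  rhs(p, y, k1);
  double h = 1e-3;

  for (int i = 1; i < nt; ++i) {
    const double tend = times[i];
    long iter = 0;
    while (t < tend) {
      if (++iter > 10000000L) stop("integrator failed to reach t = %g", tend);
      if (h > tend - t) h = tend - t;
      for (int j = 0; j < 3; ++j) yt[j] = y[j] + h * a21 * k1[j];
      rhs(p, yt, k2);
      for (int j = 0; j < 3; ++j) yt[j] = y[j] + h * (a31 * k1[j] + a32 * k2[j]);
      rhs(p, yt, k3);
      for (int j = 0; j < 3; ++j) yt[j] = y[j] + h * (a41 * k1[j] + a42 * k2[j] + a43 * k3[j]);
      rhs(p, yt, k4);
      for (int j = 0; j < 3; ++j) yt[j] = y[j] + h * (a51 * k1[j] + a52 * k2[j] + a53 * k3[j] + a54 * k4[j]);
      rhs(p, yt, k5);
      for (int j = 0; j < 3; ++j) yt[j] = y[j] + h * (a61 * k1[j] + a62 * k2[j] + a63 * k3[j] + a64 * k4[j] + a65 * k5[j]);
      rhs(p, yt, k6);
      for (int j = 0; j < 3; ++j) ynew[j] = y[j] + h * (b1 * k1[j] + b3 * k3[j] + b4 * k4[j] + b5 * k5[j] + b6 * k6[j]);
      rhs(p, ynew, k7);

      double errnorm = 0.0;
      for (int j = 0; j < 3; ++j) {
        const double err = h * (e1 * k1[j] + e3 * k3[j] + e4 * k4[j] +
                                e5 * k5[j] + e6 * k6[j] + e7 * k7[j]);
        const double sc = atol + rtol * std::max(std::fabs(y[j]), std::fabs(ynew[j]));
        const double r = err / sc;
        errnorm += r * r;
      }
      errnorm = std::sqrt(errnorm / 3.0);

      if (errnorm <= 1.0) {
        t += h;
        for (int j = 0; j < 3; ++j) { y[j] = ynew[j]; k1[j] = k7[j]; }  // FSAL
      }
      double fac = 0.9 * std::pow(errnorm > 1e-30 ? errnorm : 1e-30, -0.2);
      if (fac > 5.0) fac = 5.0;
      if (fac < 0.2) fac = 0.2;
      h *= fac;
      if (h < 1e-12) stop("step size underflow in kinetics integrator");
    }
    out(i, 0) = y[0]; out(i, 1) = y[1]; out(i, 2) = y[2];
  }
  return out;
}
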