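#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Balloon/Windkessel hemodynamic forward model, one independent four-state
// system (vasodilatory signal s, inflow f, volume v, deoxyhemoglobin q) per
// node, driven by the neural amplitude signal. Heun integration at the
// sampling step of the input (1 ms for 1 kHz input). BOLD observation:
//   y = V0 * (k1 (1 - q) + k2 (1 - q/v) + k3 (1 - v))
// with k1 = 7 rho, k2 = 2, k3 = 2 rho - 0.2.
// [[Rcpp::export(name = ".balloon_windkessel")]]
NumericMatrix balloon_windkessel_cpp(NumericMatrix neural, double dt,
                                     double kappa, double gamma_f,
                                     double tau_h, double alpha, double rho,
                                     double V0, double input_gain) {
  const int n = neural.nrow(), T = neural.ncol();
  NumericMatrix bold(n, T);
  const double ialpha = 1.0 / alpha;
  const double k1 = 7.0 * rho, k2 = 2.0, k3 = 2.0 * rho - 0.2;

  for (int i = 0; i < n; ++i) {
    double s = 0.0, f = 1.0, v = 1.0, q = 1.0;
    for (int t = 0; t < T; ++t) {
      bold(i, t) = V0 * (k1 * (1.0 - q) + k2 * (1.0 - q / v)
                         + k3 * (1.0 - v));
      double z0 = input_gain * neural(i, t);
      double z1 = input_gain * neural(i, t + 1 < T ? t + 1 : t);

      // stage 1
      double vi = std::pow(v, ialpha);
      double Ef = 1.0 - std::pow(1.0 - rho, 1.0 / f);
      double ds1 = z0 - kappa * s - gamma_f * (f - 1.0);
      double df1 = s;
      double dv1 = (f - vi) / tau_h;
      double dq1 = (f * Ef / rho - vi * q / v) / tau_h;

      double sp = s + dt * ds1, fp = f + dt * df1;
      double vp = v + dt * dv1, qp = q + dt * dq1;
      if (fp <= 0 || vp <= 0 || qp <= 0)
        stop("hemodynamic state left the positive domain at node %d, step %d",
             i + 1, t + 1);

      // stage 2
      double vip = std::pow(vp, ialpha);
      double Efp = 1.0 - std::pow(1.0 - rho, 1.0 / fp);
      double ds2 = z1 - kappa * sp - gamma_f * (fp - 1.0);
      double df2 = sp;
      double dv2 = (fp - vip) / tau_h;
      double dq2 = (fp * Efp / rho - vip * qp / vp) / tau_h;

      s += 0.5 * dt * (ds1 + ds2);
      f += 0.5 * dt * (df1 + df2);
      v += 0.5 * dt * (dv1 + dv2);
      q += 0.5 * dt * (dq1 + dq2);
      if (!(std::isfinite(s) && f > 0 && v > 0 && q > 0))
        stop("hemodynamic state left the positive domain at node %d, step %d",
             i + 1, t + 1);
    }
  }
  return bold;
}
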