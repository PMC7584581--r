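#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Delay-coupled phase-oscillator integration (Heun predictor-corrector).
//
// dtheta_i/dt = omega + sum_e kc_e * sin(theta_j(t - tau_e) - theta_i(t))
//
// Delays are realized as integer-step lookups into a circular history of
// sin/cos(theta). The coupling term is expanded as
//   sin(a - b) = sin(a) cos(b) - cos(a) sin(b)
// so each stage needs only per-node delayed sums A_i = sum kc sin(theta_j,del)
// and B_i = sum kc cos(theta_j,del), which are independent of the current
// state. For lag >= 1 edges the stage-2 sums of step t equal the stage-1 sums
// of step t+1 and are cached; lag-0 edges are re-evaluated per stage (they
// read the predictor slot in stage 2, which is what Heun requires).
//
// edges_from/edges_to are 0-based; `lag` in integration steps.
// History slot t+1 temporarily holds predictor sin/cos between the stages.
// [[Rcpp::export(name = ".kuramoto_heun")]]
List kuramoto_heun(int n, IntegerVector edges_from, IntegerVector edges_to,
                   NumericVector kc, IntegerVector lag, NumericVector theta0,
                   double dt, double omega, int n_steps, int n_transient,
                   int record_every) {
  const int ne = edges_from.size();
  int maxlag = 0;
  for (int e = 0; e < ne; ++e) if (lag[e] > maxlag) maxlag = lag[e];
  const int B = maxlag + 2;

  std::vector<double> hs((size_t)n * B), hc((size_t)n * B);
  std::vector<double> theta(theta0.begin(), theta0.end());

  // split edges by lag so the delayed-sum cache stays valid
  std::vector<int> e1_from, e1_to, e1_lag;  // lag >= 1
  std::vector<double> e1_kc;
  std::vector<int> e0_from, e0_to;          // lag == 0
  std::vector<double> e0_kc;
  for (int e = 0; e < ne; ++e) {
    if (lag[e] >= 1) {
      e1_from.push_back(edges_from[e]); e1_to.push_back(edges_to[e]);
      e1_lag.push_back(lag[e]); e1_kc.push_back(kc[e]);
    } else {
      e0_from.push_back(edges_from[e]); e0_to.push_back(edges_to[e]);
      e0_kc.push_back(kc[e]);
    }
  }
  const int ne1 = (int)e1_from.size(), ne0 = (int)e0_from.size();

  // initial history: uncoupled backward rotation theta(-s) = theta0 - omega*s
  for (int m = 0; m <= maxlag; ++m) {
    int slot = ((-m) % B + B) % B;
    for (int i = 0; i < n; ++i) {
      double th = theta0[i] - omega * dt * m;
      hs[(size_t)slot * n + i] = std::sin(th);
      hc[(size_t)slot * n + i] = std::cos(th);
    }
  }

  const int n_keep = n_steps - n_transient;
  NumericVector r_series(n_keep + 1);
  int n_rec = 0;
  NumericMatrix theta_rec;
  if (record_every > 0) {
    n_rec = n_keep / record_every + 1;
    theta_rec = NumericMatrix(n, n_rec);
  }
  int rec_i = 0;

  std::vector<double> A1(n), B1(n), A2(n), B2(n), f1(n), f2(n), thp(n);
  std::vector<double> sp(n), cp(n);

  // stage-1 delayed sums for step 0 (lag >= 1 edges)
  std::fill(A1.begin(), A1.end(), 0.0);
  std::fill(B1.begin(), B1.end(), 0.0);
  for (int e = 0; e < ne1; ++e) {
    int slot = ((0 - e1_lag[e]) % B + B) % B;
    A1[e1_from[e]] += e1_kc[e] * hs[(size_t)slot * n + e1_to[e]];
    B1[e1_from[e]] += e1_kc[e] * hc[(size_t)slot * n + e1_to[e]];
  }

  const double TWO_PI = 2.0 * M_PI;
  auto record_state = [&](int t) {
    // t is a post-transient step index (0-based)
    int slot = (t + n_transient) % B;
    double ssum = 0.0, csum = 0.0;
    for (int i = 0; i < n; ++i) {
      ssum += hs[(size_t)slot * n + i];
      csum += hc[(size_t)slot * n + i];
    }
    r_series[t] = std::sqrt(ssum * ssum + csum * csum) / n;
    if (record_every > 0 && t % record_every == 0 && rec_i < n_rec) {
      for (int i = 0; i < n; ++i) {
        double w = theta[i] - TWO_PI * std::floor(theta[i] / TWO_PI);
        if (w >= TWO_PI) w = 0.0;
        theta_rec(i, rec_i) = w;
      }
      ++rec_i;
    }
  };

  if (n_transient == 0) record_state(0);

  for (int t = 0; t < n_steps; ++t) {
    const int slot_t = ((t % B) + B) % B;
    const int slot_t1 = ((t + 1) % B + B) % B;

    // stage 1: add lag-0 contributions (read slot t, corrected values)
    for (int i = 0; i < n; ++i) { A2[i] = 0.0; B2[i] = 0.0; }
    if (ne0 > 0) {
      for (int e = 0; e < ne0; ++e) {
        A1[e0_from[e]] += e0_kc[e] * hs[(size_t)slot_t * n + e0_to[e]];
        B1[e0_from[e]] += e0_kc[e] * hc[(size_t)slot_t * n + e0_to[e]];
      }
    }
    for (int i = 0; i < n; ++i) {
      double si = hs[(size_t)slot_t * n + i], ci = hc[(size_t)slot_t * n + i];
      f1[i] = omega + A1[i] * ci - B1[i] * si;
      double p = theta[i] + dt * f1[i];
      thp[i] = p;
      sp[i] = std::sin(p); cp[i] = std::cos(p);
      hs[(size_t)slot_t1 * n + i] = sp[i];
      hc[(size_t)slot_t1 * n + i] = cp[i];
    }

    // stage-2 delayed sums at time t+1 (lag >= 1: corrected history)
    for (int e = 0; e < ne1; ++e) {
      int slot = ((t + 1 - e1_lag[e]) % B + B) % B;
      A2[e1_from[e]] += e1_kc[e] * hs[(size_t)slot * n + e1_to[e]];
      B2[e1_from[e]] += e1_kc[e] * hc[(size_t)slot * n + e1_to[e]];
    }
    // cache for next step's stage 1 before adding lag-0 (predictor) terms
    std::swap(A1, A2); std::swap(B1, B2);
    if (ne0 > 0) {
      std::vector<double> A0(n, 0.0), B0(n, 0.0);
      for (int e = 0; e < ne0; ++e) {
        A0[e0_from[e]] += e0_kc[e] * sp[e0_to[e]];
        B0[e0_from[e]] += e0_kc[e] * cp[e0_to[e]];
      }
      for (int i = 0; i < n; ++i) {
        f2[i] = omega + (A1[i] + A0[i]) * cp[i] - (B1[i] + B0[i]) * sp[i];
      }
    } else {
      for (int i = 0; i < n; ++i)
        f2[i] = omega + A1[i] * cp[i] - B1[i] * sp[i];
    }

    for (int i = 0; i < n; ++i) {
      theta[i] += 0.5 * dt * (f1[i] + f2[i]);
      hs[(size_t)slot_t1 * n + i] = std::sin(theta[i]);
      hc[(size_t)slot_t1 * n + i] = std::cos(theta[i]);
    }

    if ((t & 0x3FFF) == 0) {
      for (int i = 0; i < n; ++i)
        if (!std::isfinite(theta[i]))
          stop("phase integration diverged (non-finite phase) at step %d", t);
    }
    int tk = t + 1 - n_transient;
    if (tk >= 0) record_state(tk);
  }
  for (int i = 0; i < n; ++i)
    if (!std::isfinite(theta[i]))
      stop("phase integration diverged (non-finite phase) at final step");

  double rsum = 0.0;
  for (int t = 0; t <= n_keep; ++t) rsum += r_series[t];
  double r_mean = rsum / (n_keep + 1);

  List out = List::create(_["r"] = r_series, _["r_mean"] = r_mean);
  if (record_every > 0) out["theta"] = theta_rec;
  return out;
}
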