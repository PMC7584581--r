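#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Louvain maximization of the signed modularity quality function
//
//   Q* = (1/v+) sum_ij (w+_ij - g e+_ij) d_ij
//        - (1/(v+ + v-)) sum_ij (w-_ij - g e-_ij) d_ij ,
//   e+-_ij = s+-_i s+-_j / v+- ,
//
// written as Q* = sum_ij M_ij d_ij for a dense symmetric modularity matrix M.
// The negative term is dropped when the network has no negative weights.
// Restart randomization is the node visiting order (R RNG, so set.seed()
// controls it); ties go to the first encountered best community.

static double phase_one(std::vector<double> &M, int m,
                        std::vector<int> &comm, const std::vector<int> &order) {
  double gain_total = 0.0;
  bool improved = true;
  std::vector<double> S(m);
  while (improved) {
    improved = false;
    for (int oi = 0; oi < m; ++oi) {
      int i = order[oi];
      std::fill(S.begin(), S.end(), 0.0);
      const double *row = &M[(size_t)i * m];
      for (int j = 0; j < m; ++j)
        if (j != i) S[comm[j]] += row[j];
      int c0 = comm[i];
      double best_gain = 0.0;
      int best_c = c0;
      for (int c = 0; c < m; ++c) {
        if (c == c0) continue;
        double g = 2.0 * (S[c] - S[c0]);
        if (g > best_gain + 1e-12) { best_gain = g; best_c = c; }
      }
      if (best_c != c0) {
        comm[i] = best_c;
        gain_total += best_gain;
        improved = true;
      }
    }
  }
  return gain_total;
}

static void relabel(std::vector<int> &comm, int &k) {
  std::vector<int> map(comm.size(), -1);
  k = 0;
  for (size_t i = 0; i < comm.size(); ++i) {
    if (map[comm[i]] < 0) map[comm[i]] = k++;
    comm[i] = map[comm[i]];
  }
}

// [[Rcpp::export(name = ".louvain_signed")]]
List louvain_signed(NumericMatrix W, double gamma, int n_restarts) {
  const int n = W.nrow();
  // build the signed modularity matrix
  std::vector<double> sp(n, 0.0), sn(n, 0.0);
  double vp = 0.0, vn = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      double w = W(i, j);
      if (w > 0) { sp[i] += w; vp += w; }
      else if (w < 0) { sn[i] -= w; vn -= w; }
    }
  if (vp <= 0) stop("network has no positive weights");
  std::vector<double> M((size_t)n * n);
  const double cpos = 1.0 / vp, cneg = (vn > 0) ? 1.0 / (vp + vn) : 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      double w = W(i, j);
      double wp = w > 0 ? w : 0.0, wn = w < 0 ? -w : 0.0;
      double m = cpos * (wp - gamma * sp[i] * sp[j] / vp);
      if (vn > 0) m -= cneg * (wn - gamma * sn[i] * sn[j] / vn);
      M[(size_t)i * n + j] = m;
    }

  double best_q = R_NegInf;
  IntegerVector best_memb(n);

  for (int rs = 0; rs < n_restarts; ++rs) {
    // membership of original nodes in current aggregated communities
    std::vector<int> node2agg(n);
    for (int i = 0; i < n; ++i) node2agg[i] = i;
    std::vector<double> Mc(M);
    int m = n;

    while (true) {
      std::vector<int> comm(m);
      for (int i = 0; i < m; ++i) comm[i] = i;
      std::vector<int> order(m);
      for (int i = 0; i < m; ++i) order[i] = i;
      // Fisher-Yates with R's RNG
      for (int i = m - 1; i > 0; --i) {
        int j = (int)(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(order[i], order[j]);
      }
      double gain = phase_one(Mc, m, comm, order);
      int k;
      relabel(comm, k);
      if (gain <= 1e-12 || k == m) break;
      // aggregate
      std::vector<double> Magg((size_t)k * k, 0.0);
      for (int i = 0; i < m; ++i)
        for (int j = 0; j < m; ++j)
          Magg[(size_t)comm[i] * k + comm[j]] += Mc[(size_t)i * m + j];
      for (int i = 0; i < n; ++i) node2agg[i] = comm[node2agg[i]];
      Mc = std::move(Magg);
      m = k;
    }

    // final local sweep result = node2agg; compute Q* on the original matrix
    double q = 0.0;
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        if (node2agg[i] == node2agg[j]) q += M[(size_t)i * n + j];
    if (q > best_q) {
      best_q = q;
      for (int i = 0; i < n; ++i) best_memb[i] = node2agg[i] + 1;
    }
  }

  // canonical order-of-first-appearance labels
  std::vector<int> map(n + 1, 0);
  int k = 0;
  for (int i = 0; i < n; ++i) {
    if (map[best_memb[i]] == 0) map[best_memb[i]] = ++k;
    best_memb[i] = map[best_memb[i]];
  }
  return List::create(_["membership"] = best_memb, _["q"] = best_q,
                      _["n_communities"] = k);
}
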