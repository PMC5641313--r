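#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "rng.h"

using namespace Rcpp;

// Simulated annealing over binary binding-site occupancies A (n_types x n).
// Mean-field forward map: M_ij = min(sat, |i-j|^(-decay) * (1 + enrich * C_ij))
// with C = A^T A. Cost = mean_{i<j} | M_ij / mean(M) - D_ij / mean(D) |
//                        + lambda * (#sites) / n.
// Moves flip one (type, bead) site; Metropolis acceptance, geometric cooling.

struct AnnealState {
  int n, n_types;
  double decay, enrich, sat, lambda;
  size_t npairs;
  std::vector<double> B;      // backbone, upper triangle flat
  std::vector<double> D;      // data scaled to unit mean, upper tri
  std::vector<uint8_t> A;     // n_types x n, A[t*n + i]
  std::vector<int> C;         // n x n shared-type counts (full, symmetric)
  std::vector<double> M;      // model, upper tri
  double S;                   // sum of M over upper tri
  int sites;

  inline size_t tri(int i, int j) const { // requires i < j
    return (size_t)i * n - (size_t)i * (i + 1) / 2 + (j - i - 1);
  }

  double model_entry(int i, int j, int cij) const {
    double v = B[tri(i, j)] * (1.0 + enrich * cij);
    return v < sat ? v : sat;
  }

  void rebuild() {
    std::fill(C.begin(), C.end(), 0);
    sites = 0;
    for (int t = 0; t < n_types; ++t)
      for (int i = 0; i < n; ++i)
        if (A[(size_t)t * n + i]) {
          ++sites;
          for (int j = 0; j < n; ++j)
            if (A[(size_t)t * n + j]) C[(size_t)i * n + j] += 1;
        }
    S = 0.0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double v = model_entry(i, j, C[(size_t)i * n + j]);
        M[tri(i, j)] = v;
        S += v;
      }
  }

  double data_term() const {
    double mu = S / (double)npairs;
    double inv_mu = 1.0 / mu;
    double acc = 0.0;
    for (size_t k = 0; k < npairs; ++k) acc += std::fabs(M[k] * inv_mu - D[k]);
    return acc / (double)npairs;
  }

  double cost() const {
    return data_term() + lambda * (double)sites / (double)n;
  }

  // flip site (t, b); updates C, M, S, sites in place.
  void apply_flip(int t, int b) {
    int delta = A[(size_t)t * n + b] ? -1 : 1;
    A[(size_t)t * n + b] ^= 1;
    sites += delta;
    const uint8_t *row = &A[(size_t)t * n];
    for (int j = 0; j < n; ++j) {
      if (j == b || !row[j]) continue;
      C[(size_t)b * n + j] += delta;
      C[(size_t)j * n + b] += delta;
      int i = b < j ? b : j, jj = b < j ? j : b;
      size_t k = tri(i, jj);
      double v = model_entry(i, jj, C[(size_t)b * n + j]);
      S += v - M[k];
      M[k] = v;
    }
    // diagonal C_bb changes too (not part of the cost, but kept consistent)
    C[(size_t)b * n + b] += delta;
  }
};

// [[Rcpp::export]]
List cpp_anneal(NumericMatrix data, int n_types, double decay, double enrich,
                double sat, int n_sweeps, double T_start, double T_end,
                double cooling, double lambda, int n_restarts, int seed) {
  int n = data.ncol();
  AnnealState st;
  st.n = n; st.n_types = n_types;
  st.decay = decay; st.enrich = enrich; st.sat = sat; st.lambda = lambda;
  st.npairs = (size_t)n * (n - 1) / 2;
  st.B.resize(st.npairs);
  st.D.resize(st.npairs);
  st.M.resize(st.npairs);
  st.A.assign((size_t)n_types * n, 0);
  st.C.assign((size_t)n * n, 0);

  double dsum = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      st.B[st.tri(i, j)] = std::pow((double)(j - i), -decay);
      dsum += data(i, j);
    }
  if (dsum <= 0) stop("contact map has zero off-diagonal mass; nothing to fit");
  double dmu = dsum / (double)st.npairs;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) st.D[st.tri(i, j)] = data(i, j) / dmu;

  std::vector<uint8_t> best_A;
  double best_cost = R_PosInf;
  std::vector<double> trace;
  trace.reserve((size_t)n_sweeps * n_restarts);
  int moves_per_sweep = n_types * n;

  for (int r = 0; r < n_restarts; ++r) {
    SbsRng rng((uint64_t)(unsigned int)seed * 6364136223846793005ULL +
               (uint64_t)r + 1ULL);
    // random sparse init at the density of one type per bead
    double p0 = 1.0 / (double)n_types;
    for (size_t k = 0; k < st.A.size(); ++k) st.A[k] = rng.unif() < p0 ? 1 : 0;
    st.rebuild();
    double cur = st.cost();
    if (cur < best_cost) { best_cost = cur; best_A = st.A; }

    double T0 = T_start;
    if (!(T0 > 0)) {
      // calibrate so that a typical uphill move is accepted ~50% of the time
      double acc = 0.0; int cnt = 0;
      for (int p = 0; p < 100; ++p) {
        int t = rng.unif_int(n_types), b = rng.unif_int(n);
        st.apply_flip(t, b);
        double c2 = st.cost();
        if (c2 > cur) { acc += c2 - cur; ++cnt; }
        st.apply_flip(t, b); // revert
      }
      double mean_up = cnt > 0 ? acc / cnt : 1e-3;
      T0 = mean_up / 0.6931471805599453; // ln 2
    }

    double T = T0;
    for (int sweep = 0; sweep < n_sweeps; ++sweep) {
      for (int mv = 0; mv < moves_per_sweep; ++mv) {
        int t = rng.unif_int(n_types), b = rng.unif_int(n);
        st.apply_flip(t, b);
        double c2 = st.cost();
        double dE = c2 - cur;
        if (dE <= 0.0 || rng.unif() < std::exp(-dE / T)) {
          cur = c2;
          if (cur < best_cost) {
            best_cost = cur;
            best_A = st.A;
          }
        } else {
          st.apply_flip(t, b);
        }
      }
      trace.push_back(best_cost);
      T = std::max(T_end, T * cooling);
      Rcpp::checkUserInterrupt();
    }
  }

  IntegerMatrix A_out(n_types, n);
  for (int t = 0; t < n_types; ++t)
    for (int i = 0; i < n; ++i) A_out(t, i) = best_A[(size_t)t * n + i];
  return List::create(_["abundance"] = A_out,
                      _["final_cost"] = best_cost,
                      _["cost_trace"] = NumericVector(trace.begin(), trace.end()));
}
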