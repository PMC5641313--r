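#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Steinhardt l=6 bond-orientational order. For each center particle the
// local q6 is computed from the directions to its neighbors within `cutoff`
// (minimum image in a periodic box of side `box`); the global Q6 averages
// the spherical-harmonic components over all bonds before taking the
// rotational invariant, so it vanishes for liquid-like disorder and stays
// O(1) for crystalline packings.

static const int L = 6;

// sqrt((2l+1)/(4pi) (l-m)!/(l+m)!) * P_l^m(x), m >= 0, no Condon-Shortley
static double norm_plm(int m, double x) {
  // P_6^m via stable upward recurrence on l for fixed m
  double pmm = 1.0;
  double somx2 = std::sqrt((1.0 - x) * (1.0 + x));
  for (int i = 1; i <= m; ++i) pmm *= (2.0 * i - 1.0) * somx2;
  double p_lm;
  if (m == L) p_lm = pmm;
  else {
    double pmmp1 = x * (2.0 * m + 1.0) * pmm;
    if (m + 1 == L) p_lm = pmmp1;
    else {
      double pll = 0.0;
      for (int l = m + 2; l <= L; ++l) {
        pll = ((2.0 * l - 1.0) * x * pmmp1 - (l + m - 1.0) * pmm) / (l - m);
        pmm = pmmp1; pmmp1 = pll;
      }
      p_lm = pll;
    }
  }
  double lg = std::lgamma(L - m + 1.0) - std::lgamma(L + m + 1.0);
  double norm = std::sqrt((2.0 * L + 1.0) / (4.0 * M_PI) * std::exp(lg));
  return norm * p_lm;
}

// [[Rcpp::export]]
List cpp_bond_order(NumericMatrix centers, NumericMatrix pool, double cutoff,
                    double box) {
  int nc = centers.nrow(), np = pool.nrow();
  double c2 = cutoff * cutoff, inv_box = 1.0 / box;
  NumericVector local_q6(nc, NA_REAL);
  IntegerVector n_neigh(nc);
  // global accumulators over all bonds
  double gq_re[L + 1] = {0}, gq_im[L + 1] = {0};
  long n_bonds = 0;

  for (int i = 0; i < nc; ++i) {
    double q_re[L + 1] = {0}, q_im[L + 1] = {0};
    int nb = 0;
    for (int j = 0; j < np; ++j) {
      double dx = pool(j, 0) - centers(i, 0);
      double dy = pool(j, 1) - centers(i, 1);
      double dz = pool(j, 2) - centers(i, 2);
      dx -= box * std::nearbyint(dx * inv_box);
      dy -= box * std::nearbyint(dy * inv_box);
      dz -= box * std::nearbyint(dz * inv_box);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < 1e-12 || r2 > c2) continue;
      double r = std::sqrt(r2);
      double cth = dz / r;
      double phi = std::atan2(dy, dx);
      for (int m = 0; m <= L; ++m) {
        double ylm = norm_plm(m, cth);
        double cre = ylm * std::cos(m * phi), cim = ylm * std::sin(m * phi);
        q_re[m] += cre; q_im[m] += cim;
        gq_re[m] += cre; gq_im[m] += cim;
      }
      ++nb;
    }
    n_neigh[i] = nb;
    n_bonds += nb;
    if (nb >= 3) {
      double s = 0.0;
      for (int m = 0; m <= L; ++m) {
        double a = q_re[m] / nb, b = q_im[m] / nb;
        double mod2 = a * a + b * b;
        s += (m == 0 ? 1.0 : 2.0) * mod2;
      }
      local_q6[i] = std::sqrt(4.0 * M_PI / (2.0 * L + 1.0) * s);
    }
  }

  double global_q6 = NA_REAL;
  if (n_bonds > 0) {
    double s = 0.0;
    for (int m = 0; m <= L; ++m) {
      double a = gq_re[m] / n_bonds, b = gq_im[m] / n_bonds;
      s += (m == 0 ? 1.0 : 2.0) * (a * a + b * b);
    }
    global_q6 = std::sqrt(4.0 * M_PI / (2.0 * L + 1.0) * s);
  }

  return List::create(_["local_q6"] = local_q6,
                      _["n_neighbors"] = n_neigh,
                      _["global_q6"] = global_q6);
}
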