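#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "rng.h"

using namespace Rcpp;

// Kremer-Grest style bead-spring force field (units: sigma = 1, kT = 1):
//   FENE bonds K = 30, R0 = 1.5 between consecutive beads (plus WCA core);
//   WCA (shifted-truncated 12-6, cutoff 2^(1/6)) between all particle pairs;
//   bead-binder pairs with cognate type: truncated-shifted 12-6 well,
//   depth = affinity[type] * abundance[type][bead], cutoff attr_cutoff.
static const double FENE_K = 30.0;
static const double FENE_R0 = 1.5;
static const double WCA_CUT = 1.1224620483093730; // 2^(1/6)
static const double SKIN = 0.4;

struct System {
  int n_beads, n_binders, n;
  double box, inv_box;
  std::vector<double> x, y, z;    // unwrapped positions
  std::vector<double> vx, vy, vz;
  std::vector<double> fx, fy, fz;
  // pair attraction depth, indexed [binder][bead]; 0 => plain WCA
  std::vector<double> eps_bb;
  double attr_cut;
  // neighbor list
  std::vector<int> nl_i, nl_j;
  std::vector<double> ref_x, ref_y, ref_z;
  double e_bond, e_pair;
  int bad_bond_step;

  inline void min_image(double &dx, double &dy, double &dz) const {
    dx -= box * std::nearbyint(dx * inv_box);
    dy -= box * std::nearbyint(dy * inv_box);
    dz -= box * std::nearbyint(dz * inv_box);
  }

  inline double eps_attr(int i, int j) const {
    // i < n_beads bead, j >= n_beads binder (or swapped); else 0
    if (i < n_beads && j >= n_beads) return eps_bb[(size_t)(j - n_beads) * n_beads + i];
    if (j < n_beads && i >= n_beads) return eps_bb[(size_t)(i - n_beads) * n_beads + j];
    return 0.0;
  }

  void build_neighbors() {
    nl_i.clear(); nl_j.clear();
    double rl = attr_cut + SKIN;
    double rl2 = rl * rl;
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        if (j == i + 1 && j < n_beads) continue; // bonded pair handled separately
        double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
        min_image(dx, dy, dz);
        if (dx * dx + dy * dy + dz * dz < rl2) { nl_i.push_back(i); nl_j.push_back(j); }
      }
    }
    ref_x = x; ref_y = y; ref_z = z;
  }

  bool needs_rebuild() const {
    double lim = 0.25 * SKIN * SKIN; // (skin/2)^2
    for (int i = 0; i < n; ++i) {
      double dx = x[i] - ref_x[i], dy = y[i] - ref_y[i], dz = z[i] - ref_z[i];
      if (dx * dx + dy * dy + dz * dz > lim) return true;
    }
    return false;
  }

  // returns false on FENE overstretch
  bool compute_forces() {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    e_bond = 0.0; e_pair = 0.0;
    const double R02 = FENE_R0 * FENE_R0;
    const double wca2 = WCA_CUT * WCA_CUT;
    // bonds: FENE + WCA between consecutive beads
    for (int i = 0; i + 1 < n_beads; ++i) {
      int j = i + 1;
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      min_image(dx, dy, dz);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= R02) return false;
      double denom = 1.0 - r2 / R02;
      // FENE: V = -0.5 K R0^2 ln(1 - r^2/R0^2); F/r = -K / (1 - r^2/R0^2)
      double fr = -FENE_K / denom;
      e_bond += -0.5 * FENE_K * R02 * std::log(denom);
      if (r2 < wca2) {
        double inv2 = 1.0 / r2;
        double inv6 = inv2 * inv2 * inv2;
        fr += 24.0 * inv2 * inv6 * (2.0 * inv6 - 1.0);
        e_bond += 4.0 * inv6 * (inv6 - 1.0) + 1.0;
      }
      fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
      fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
    }
    // nonbonded
    const double ac2 = attr_cut * attr_cut;
    double inv_ac2 = 1.0 / ac2;
    double inv_ac6 = inv_ac2 * inv_ac2 * inv_ac2;
    double shift_attr = 4.0 * inv_ac6 * (inv_ac6 - 1.0); // per unit epsilon
    size_t m = nl_i.size();
    for (size_t k = 0; k < m; ++k) {
      int i = nl_i[k], j = nl_j[k];
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      min_image(dx, dy, dz);
      double r2 = dx * dx + dy * dy + dz * dz;
      double eps = eps_attr(i, j);
      double fr = 0.0;
      if (eps > 0.0) {
        if (r2 < ac2) {
          double inv2 = 1.0 / r2;
          double inv6 = inv2 * inv2 * inv2;
          fr = 24.0 * eps * inv2 * inv6 * (2.0 * inv6 - 1.0);
          e_pair += eps * (4.0 * inv6 * (inv6 - 1.0) - shift_attr);
        }
      } else if (r2 < wca2) {
        double inv2 = 1.0 / r2;
        double inv6 = inv2 * inv2 * inv2;
        fr = 24.0 * inv2 * inv6 * (2.0 * inv6 - 1.0);
        e_pair += 4.0 * inv6 * (inv6 - 1.0) + 1.0;
      }
      if (fr != 0.0) {
        fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
        fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
      }
    }
    return true;
  }
};

// [[Rcpp::export]]
List cpp_run_langevin(NumericMatrix bead0, NumericMatrix binder0,
                      IntegerMatrix abundance, IntegerVector binder_type,
                      NumericVector affinity, double box, double dt,
                      double friction, double kT, int n_steps, int save_stride,
                      int seed, double attr_cutoff) {
  System S;
  S.n_beads = bead0.nrow();
  S.n_binders = binder0.nrow();
  S.n = S.n_beads + S.n_binders;
  S.box = box; S.inv_box = 1.0 / box;
  S.attr_cut = attr_cutoff;
  S.x.resize(S.n); S.y.resize(S.n); S.z.resize(S.n);
  S.vx.assign(S.n, 0.0); S.vy.assign(S.n, 0.0); S.vz.assign(S.n, 0.0);
  S.fx.resize(S.n); S.fy.resize(S.n); S.fz.resize(S.n);
  for (int i = 0; i < S.n_beads; ++i) {
    S.x[i] = bead0(i, 0); S.y[i] = bead0(i, 1); S.z[i] = bead0(i, 2);
  }
  for (int i = 0; i < S.n_binders; ++i) {
    S.x[S.n_beads + i] = binder0(i, 0);
    S.y[S.n_beads + i] = binder0(i, 1);
    S.z[S.n_beads + i] = binder0(i, 2);
  }
  // pairwise attraction depths
  S.eps_bb.assign((size_t)S.n_binders * S.n_beads, 0.0);
  int n_types = abundance.nrow();
  for (int b = 0; b < S.n_binders; ++b) {
    int t = binder_type[b];
    if (t < 0 || t >= n_types) stop("binder type out of range");
    double aff = affinity[t];
    for (int i = 0; i < S.n_beads; ++i) {
      S.eps_bb[(size_t)b * S.n_beads + i] = aff * abundance(t, i);
    }
  }

  SbsRng rng((uint64_t)(unsigned int)seed * 0x9E3779B97F4A7C15ULL + 1ULL);
  // Maxwell-Boltzmann initial velocities
  double sd0 = std::sqrt(kT);
  for (int i = 0; i < S.n; ++i) {
    S.vx[i] = sd0 * rng.gauss();
    S.vy[i] = sd0 * rng.gauss();
    S.vz[i] = sd0 * rng.gauss();
  }

  S.build_neighbors();
  if (!S.compute_forces())
    stop("bond overstretched in the initial conformation");

  // BAOAB constants (mass = 1)
  double c1 = std::exp(-friction * dt);
  double c2 = std::sqrt((1.0 - c1 * c1) * kT);
  double hdt = 0.5 * dt;

  int n_frames = n_steps / std::max(1, save_stride) + 1;
  List frames(n_frames);
  NumericVector f_time(n_frames);
  NumericVector e_bond_v(n_frames), e_pair_v(n_frames), e_kin_v(n_frames);
  int fi = 0;

  auto save_frame = [&](int step) {
    NumericMatrix bp(S.n_beads, 3), sp(S.n_binders, 3);
    double ekin = 0.0;
    for (int i = 0; i < S.n_beads; ++i) {
      bp(i, 0) = S.x[i]; bp(i, 1) = S.y[i]; bp(i, 2) = S.z[i];
    }
    for (int i = 0; i < S.n_binders; ++i) {
      sp(i, 0) = S.x[S.n_beads + i];
      sp(i, 1) = S.y[S.n_beads + i];
      sp(i, 2) = S.z[S.n_beads + i];
    }
    for (int i = 0; i < S.n; ++i)
      ekin += 0.5 * (S.vx[i] * S.vx[i] + S.vy[i] * S.vy[i] + S.vz[i] * S.vz[i]);
    for (int i = 0; i < S.n; ++i) {
      if (!std::isfinite(S.x[i]) || !std::isfinite(S.y[i]) || !std::isfinite(S.z[i]))
        stop("non-finite coordinate at step %d; reduce the timestep", step);
    }
    frames[fi] = List::create(_["bead_positions"] = bp,
                              _["binder_positions"] = sp,
                              _["time"] = step * dt);
    f_time[fi] = step * dt;
    e_bond_v[fi] = S.e_bond; e_pair_v[fi] = S.e_pair; e_kin_v[fi] = ekin;
    ++fi;
  };

  save_frame(0);

  for (int step = 1; step <= n_steps; ++step) {
    // B
    for (int i = 0; i < S.n; ++i) {
      S.vx[i] += hdt * S.fx[i]; S.vy[i] += hdt * S.fy[i]; S.vz[i] += hdt * S.fz[i];
    }
    // A
    for (int i = 0; i < S.n; ++i) {
      S.x[i] += hdt * S.vx[i]; S.y[i] += hdt * S.vy[i]; S.z[i] += hdt * S.vz[i];
    }
    // O
    for (int i = 0; i < S.n; ++i) {
      S.vx[i] = c1 * S.vx[i] + c2 * rng.gauss();
      S.vy[i] = c1 * S.vy[i] + c2 * rng.gauss();
      S.vz[i] = c1 * S.vz[i] + c2 * rng.gauss();
    }
    // A
    for (int i = 0; i < S.n; ++i) {
      S.x[i] += hdt * S.vx[i]; S.y[i] += hdt * S.vy[i]; S.z[i] += hdt * S.vz[i];
    }
    // B with fresh forces
    if (S.needs_rebuild()) S.build_neighbors();
    if (!S.compute_forces())
      stop("bond overstretched (> 1.5 sigma) at step %d; reduce the timestep",
           step);
    for (int i = 0; i < S.n; ++i) {
      S.vx[i] += hdt * S.fx[i]; S.vy[i] += hdt * S.fy[i]; S.vz[i] += hdt * S.fz[i];
    }
    if (save_stride > 0 && step % save_stride == 0) save_frame(step);
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["frames"] = frames,
                      _["times"] = f_time,
                      _["e_bond"] = e_bond_v,
                      _["e_pair"] = e_pair_v,
                      _["e_kinetic"] = e_kin_v);
}
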