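// Force kernel and integrators for the chromosome copolymer model.
//
// Reduced units throughout: sigma = 1, k_B T = temperature argument (1 by
// default), bead mass m = 1 (Langevin). The chain is a Kremer-Grest style
// bead-spring polymer: FENE bonds (+ WCA core inside the bond term) between
// consecutive beads and between loop-anchor pairs, and a truncated-shifted
// 12-6 Lennard-Jones pair interaction between all non-bonded pairs, with the
// well depth selected by the epigenetic labels of the pair (AA/BB: eps,
// AB: eps / eps_ratio). Pair LJ is excluded for directly bonded pairs
// (LAMMPS `special_bonds fene` convention).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <functional>
#include <random>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

namespace {

struct Model {
  int n;
  std::vector<int> label;            // 0 = A, 1 = B
  std::vector<std::pair<int,int> > loops;
  double eps_aa, eps_bb, eps_ab;
  double rc;                         // LJ cutoff (sigma units)
  double fene_k, fene_r0, wca_eps;
  double loop_fcap, loop_rswitch, loop_ushift;  // capped-force loop extension
  bool ideal;                        // harmonic bonds, no pair interactions
  double harm_k, harm_r0;
  std::unordered_set<int64_t> excl;        // bonded pairs (energy eval)
  std::vector<std::vector<int> > loop_nbr; // per-bead loop partners (force)

  double eps_of(int i, int j) const {
    if (label[i] == label[j]) return label[i] == 0 ? eps_aa : eps_bb;
    return eps_ab;
  }

  bool excluded(int i, int j) const {  // fast path for the force loop
    if (j - i == 1 || i - j == 1) return true;
    const std::vector<int> &v = loop_nbr[i];
    for (size_t q = 0; q < v.size(); ++q)
      if (v[q] == j) return true;
    return false;
  }
};

inline int64_t pair_key(int i, int j, int n) {
  return (int64_t)std::min(i, j) * n + std::max(i, j);
}

Model build_model(const IntegerVector &labels, const IntegerMatrix &loops,
                  const List &pars, bool ideal) {
  Model m;
  m.n = labels.size();
  m.label.assign(labels.begin(), labels.end());
  for (int k = 0; k < loops.nrow(); ++k)
    m.loops.push_back(std::make_pair(loops(k, 0), loops(k, 1)));
  m.eps_aa = as<double>(pars["eps_aa"]);
  m.eps_bb = as<double>(pars["eps_bb"]);
  m.eps_ab = as<double>(pars["eps_ab"]);
  m.rc = as<double>(pars["cutoff"]);
  m.fene_k = as<double>(pars["fene_k"]);
  m.fene_r0 = as<double>(pars["fene_r0"]);
  m.wca_eps = as<double>(pars["wca_eps"]);
  m.harm_k = as<double>(pars["harm_k"]);
  m.harm_r0 = as<double>(pars["harm_r0"]);
  m.loop_fcap = as<double>(pars["loop_fcap"]);
  // radius where the FENE force reaches the cap: (fcap/R0^2) r^2 + k r = fcap
  {
    double a = m.loop_fcap / (m.fene_r0 * m.fene_r0);
    double rs = (-m.fene_k +
                 std::sqrt(m.fene_k * m.fene_k + 4.0 * a * m.loop_fcap)) /
                (2.0 * a);
    m.loop_rswitch = rs;
    double r02 = m.fene_r0 * m.fene_r0;
    m.loop_ushift = -0.5 * m.fene_k * r02 * std::log(1.0 - rs * rs / r02);
  }
  m.ideal = ideal;
  for (int i = 0; i + 1 < m.n; ++i) m.excl.insert(pair_key(i, i + 1, m.n));
  m.loop_nbr.resize(m.n);
  for (size_t k = 0; k < m.loops.size(); ++k) {
    m.excl.insert(pair_key(m.loops[k].first, m.loops[k].second, m.n));
    m.loop_nbr[m.loops[k].first].push_back(m.loops[k].second);
    m.loop_nbr[m.loops[k].second].push_back(m.loops[k].first);
  }
  return m;
}

// Truncated-shifted LJ energy and force factor F/r for a label pair.
inline void lj_pair(double r2, double eps, double rc, double &u,
                    double &f_over_r) {
  const double rc2 = rc * rc;
  if (eps <= 0.0 || r2 >= rc2) { u = 0.0; f_over_r = 0.0; return; }
  double sr2 = 1.0 / r2, sr6 = sr2 * sr2 * sr2;
  double src2 = 1.0 / rc2, src6 = src2 * src2 * src2;
  u = 4.0 * eps * (sr6 * sr6 - sr6) - 4.0 * eps * (src6 * src6 - src6);
  f_over_r = 24.0 * eps * (2.0 * sr6 * sr6 - sr6) * sr2;
}

// WCA (purely repulsive shifted LJ, cutoff 2^(1/6)).
inline void wca_pair(double r2, double eps, double &u, double &f_over_r) {
  const double rc2 = std::pow(2.0, 1.0 / 3.0);
  if (eps <= 0.0 || r2 >= rc2) { u = 0.0; f_over_r = 0.0; return; }
  double sr2 = 1.0 / r2, sr6 = sr2 * sr2 * sr2;
  u = 4.0 * eps * (sr6 * sr6 - sr6) + eps;
  f_over_r = 24.0 * eps * (2.0 * sr6 * sr6 - sr6) * sr2;
}

// FENE bond; returns false when r is outside the bond domain.
inline bool fene_pair(double r2, double k, double r0, double &u,
                      double &f_over_r) {
  const double r02 = r0 * r0;
  if (r2 >= r02) return false;
  u = -0.5 * k * r02 * std::log(1.0 - r2 / r02);
  f_over_r = -k / (1.0 - r2 / r02);
  return true;
}

class NeighborList {
public:
  NeighborList(double cutoff, double skin) : cut_(cutoff), skin_(skin) {}

  void build(const std::vector<double> &x, int n) {
    pairs_.clear();
    ref_ = x;
    const double cell = cut_ + skin_;
    const double r2max = cell * cell;
    std::unordered_map<int64_t, std::vector<int> > grid;
    grid.reserve(2 * n);
    for (int i = 0; i < n; ++i) grid[cell_key(x, i, cell)].push_back(i);
    for (int i = 0; i < n; ++i) {
      int cx = (int)std::floor(x[3 * i] / cell);
      int cy = (int)std::floor(x[3 * i + 1] / cell);
      int cz = (int)std::floor(x[3 * i + 2] / cell);
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            std::unordered_map<int64_t, std::vector<int> >::const_iterator it =
                grid.find(key(cx + dx, cy + dy, cz + dz));
            if (it == grid.end()) continue;
            const std::vector<int> &cellv = it->second;
            for (size_t q = 0; q < cellv.size(); ++q) {
              int j = cellv[q];
              if (j <= i) continue;
              double r2 = dist2(x, i, j);
              if (r2 < r2max) { pairs_.push_back(i); pairs_.push_back(j); }
            }
          }
    }
    // canonical (i, j) order so force accumulation is independent of the
    // cell partitioning (and hence of the skin) to the last bit
    std::vector<int64_t> keys(pairs_.size() / 2);
    for (size_t q = 0; q < keys.size(); ++q)
      keys[q] = ((int64_t)pairs_[2 * q] << 32) | (int64_t)pairs_[2 * q + 1];
    std::sort(keys.begin(), keys.end());
    for (size_t q = 0; q < keys.size(); ++q) {
      pairs_[2 * q] = (int)(keys[q] >> 32);
      pairs_[2 * q + 1] = (int)(keys[q] & 0xffffffff);
    }
  }

  bool stale(const std::vector<double> &x, int n) const {
    const double lim = 0.25 * skin_ * skin_;  // (skin/2)^2
    for (int i = 0; i < n; ++i) {
      double d2 = 0.0;
      for (int c = 0; c < 3; ++c) {
        double d = x[3 * i + c] - ref_[3 * i + c];
        d2 += d * d;
      }
      if (d2 > lim) return true;
    }
    return false;
  }

  const std::vector<int> &pairs() const { return pairs_; }

private:
  static double dist2(const std::vector<double> &x, int i, int j) {
    double s = 0.0;
    for (int c = 0; c < 3; ++c) {
      double d = x[3 * i + c] - x[3 * j + c];
      s += d * d;
    }
    return s;
  }
  static int64_t key(int ix, int iy, int iz) {
    return ((int64_t)(ix + (1 << 20)) << 42) |
           ((int64_t)(iy + (1 << 20)) << 21) | (int64_t)(iz + (1 << 20));
  }
  static int64_t cell_key(const std::vector<double> &x, int i, double cell) {
    return key((int)std::floor(x[3 * i] / cell),
               (int)std::floor(x[3 * i + 1] / cell),
               (int)std::floor(x[3 * i + 2] / cell));
  }
  double cut_, skin_;
  std::vector<int> pairs_;
  std::vector<double> ref_;
};

// Accumulate all forces; returns index (1-based) of first overstretched bond
// or 0 on success.
int compute_forces(const Model &m, const std::vector<double> &x,
                   std::vector<double> &f, const NeighborList &nl) {
  std::fill(f.begin(), f.end(), 0.0);
  double u, fr;
  // chain + loop bonds
  int nb = m.n - 1 + (int)m.loops.size();
  for (int b = 0; b < nb; ++b) {
    int i, j;
    if (b < m.n - 1) { i = b; j = b + 1; }
    else { i = m.loops[b - (m.n - 1)].first; j = m.loops[b - (m.n - 1)].second; }
    double d[3], r2 = 0.0;
    for (int c = 0; c < 3; ++c) { d[c] = x[3*i+c] - x[3*j+c]; r2 += d[c]*d[c]; }
    double ftot = 0.0;
    bool is_loop = b >= m.n - 1;
    if (m.ideal) {
      double r = std::sqrt(r2);
      if (r > 1e-12) ftot = -m.harm_k * (r - m.harm_r0) / r;
    } else if (is_loop && r2 >= m.loop_rswitch * m.loop_rswitch) {
      // capped constant pull: keeps loop bonds defined at any extension
      ftot = -m.loop_fcap / std::sqrt(r2);
    } else {
      if (!fene_pair(r2, m.fene_k, m.fene_r0, u, fr)) return b + 1;
      ftot = fr;
      wca_pair(r2, m.wca_eps, u, fr);
      ftot += fr;
    }
    for (int c = 0; c < 3; ++c) { f[3*i+c] += ftot * d[c]; f[3*j+c] -= ftot * d[c]; }
  }
  if (m.ideal) return 0;
  // non-bonded pairs
  const std::vector<int> &pr = nl.pairs();
  const double rc2 = m.rc * m.rc;
  for (size_t q = 0; q < pr.size(); q += 2) {
    int i = pr[q], j = pr[q + 1];
    if (m.excluded(i, j)) continue;
    double d[3], r2 = 0.0;
    for (int c = 0; c < 3; ++c) { d[c] = x[3*i+c] - x[3*j+c]; r2 += d[c]*d[c]; }
    if (r2 >= rc2) continue;
    double eps = m.eps_of(i, j);
    if (eps > 0.0) {
      lj_pair(r2, eps, m.rc, u, fr);
    } else {
      wca_pair(r2, m.wca_eps, u, fr);
    }
    for (int c = 0; c < 3; ++c) { f[3*i+c] += fr * d[c]; f[3*j+c] -= fr * d[c]; }
  }
  return 0;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_run_bd")]]
List cpp_run_bd(NumericMatrix pos, IntegerVector labels, IntegerMatrix loops,
                List pars, int n_steps, double dt, double friction,
                double temperature, double seed, int save_every, bool ideal,
                double skin) {
  const int n = pos.nrow();
  Model m = build_model(labels, loops, pars, ideal);
  std::vector<double> x(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = pos(i, c);

  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  const double mob = dt / friction;
  const double amp = std::sqrt(2.0 * temperature * dt / friction);

  const int n_save = n_steps / save_every + 1;
  NumericVector frames(Dimension(n, 3, n_save));
  NumericVector times(n_save);
  int isave = 0;
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) frames[i + n * c] = x[3 * i + c];
  times[0] = 0.0;
  ++isave;

  NeighborList nl(m.rc, skin);
  nl.build(x, n);
  for (int step = 1; step <= n_steps; ++step) {
    if (nl.stale(x, n)) nl.build(x, n);
    int bad = compute_forces(m, x, f, nl);
    if (bad)
      stop("bond %d out of the FENE domain at step %d (numerical blow-up; reduce dt)",
           bad, step);
    for (int i = 0; i < 3 * n; ++i) x[i] += mob * f[i] + amp * gauss(rng);
    if (step % save_every == 0) {
      for (int i = 0; i < n; ++i)
        for (int c = 0; c < 3; ++c)
          frames[i + n * c + (R_xlen_t)n * 3 * isave] = x[3 * i + c];
      times[isave] = step * dt;
      ++isave;
      Rcpp::checkUserInterrupt();
    }
  }
  return List::create(_["frames"] = frames, _["times"] = times);
}

// [[Rcpp::export(name = ".cpp_run_langevin")]]
List cpp_run_langevin(NumericMatrix pos, IntegerVector labels,
                      IntegerMatrix loops, List pars, int n_steps, double dt,
                      double friction, double temperature, double seed,
                      int save_every, bool ideal, double skin) {
  const int n = pos.nrow();
  Model m = build_model(labels, loops, pars, ideal);
  std::vector<double> x(3 * n), v(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = pos(i, c);

  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  const double vsd = std::sqrt(temperature);  // m = 1
  for (int i = 0; i < 3 * n; ++i) v[i] = vsd * gauss(rng);

  // BAOAB splitting
  const double c1 = std::exp(-friction * dt);
  const double c2 = (friction > 0.0)
                        ? std::sqrt(temperature * (1.0 - c1 * c1))
                        : 0.0;

  const int n_save = n_steps / save_every + 1;
  NumericVector frames(Dimension(n, 3, n_save));
  NumericVector times(n_save), ekin(n_save);
  int isave = 0;
  double ek0 = 0.0;
  for (int i = 0; i < 3 * n; ++i) ek0 += 0.5 * v[i] * v[i];
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) frames[i + n * c] = x[3 * i + c];
  times[0] = 0.0;
  ekin[0] = ek0;
  ++isave;

  NeighborList nl(m.rc, skin);
  nl.build(x, n);
  int bad = compute_forces(m, x, f, nl);
  if (bad) stop("initial conformation has bond %d outside the FENE domain", bad);

  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < 3 * n; ++i) v[i] += 0.5 * dt * f[i];
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    if (friction > 0.0)
      for (int i = 0; i < 3 * n; ++i) v[i] = c1 * v[i] + c2 * gauss(rng);
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    if (nl.stale(x, n)) nl.build(x, n);
    bad = compute_forces(m, x, f, nl);
    if (bad)
      stop("bond %d out of the FENE domain at step %d (numerical blow-up; reduce dt)",
           bad, step);
    for (int i = 0; i < 3 * n; ++i) v[i] += 0.5 * dt * f[i];
    if (step % save_every == 0) {
      double ek = 0.0;
      for (int i = 0; i < 3 * n; ++i) ek += 0.5 * v[i] * v[i];
      for (int i = 0; i < n; ++i)
        for (int c = 0; c < 3; ++c)
          frames[i + n * c + (R_xlen_t)n * 3 * isave] = x[3 * i + c];
      times[isave] = step * dt;
      ekin[isave] = ek;
      ++isave;
      Rcpp::checkUserInterrupt();
    }
  }
  return List::create(_["frames"] = frames, _["times"] = times,
                      _["ekin"] = ekin);
}

// [[Rcpp::export(name = ".cpp_total_energy")]]
List cpp_total_energy(NumericMatrix pos, IntegerVector labels,
                      IntegerMatrix loops, List pars, bool ideal, bool shift) {
  const int n = pos.nrow();
  Model m = build_model(labels, loops, pars, ideal);
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = pos(i, c);
  double u, fr, us = 0.0, ul = 0.0, ulj = 0.0;
  int bad_bond = 0;
  int nb = n - 1 + (int)m.loops.size();
  for (int b = 0; b < nb; ++b) {
    int i, j;
    bool is_loop = b >= n - 1;
    if (!is_loop) { i = b; j = b + 1; }
    else { i = m.loops[b - (n - 1)].first; j = m.loops[b - (n - 1)].second; }
    double r2 = 0.0;
    for (int c = 0; c < 3; ++c) {
      double d = x[3*i+c] - x[3*j+c];
      r2 += d * d;
    }
    double ub = 0.0;
    if (m.ideal) {
      double r = std::sqrt(r2);
      ub = 0.5 * m.harm_k * (r - m.harm_r0) * (r - m.harm_r0);
    } else if (is_loop && r2 >= m.loop_rswitch * m.loop_rswitch) {
      ub = m.loop_ushift + m.loop_fcap * (std::sqrt(r2) - m.loop_rswitch);
    } else {
      if (!fene_pair(r2, m.fene_k, m.fene_r0, u, fr)) { bad_bond = b + 1; break; }
      ub = u;
      wca_pair(r2, m.wca_eps, u, fr);
      ub += u;
    }
    if (is_loop) ul += ub; else us += ub;
  }
  if (!bad_bond && !m.ideal) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        if (m.excl.count(pair_key(i, j, n))) continue;
        double r2 = 0.0;
        for (int c = 0; c < 3; ++c) {
          double d = x[3*i+c] - x[3*j+c];
          r2 += d * d;
        }
        double eps = m.eps_of(i, j);
        if (eps > 0.0) {
          lj_pair(r2, eps, m.rc, u, fr);
          if (!shift && u != 0.0) {
            double src2 = 1.0 / (m.rc * m.rc);
            double src6 = src2 * src2 * src2;
            u += 4.0 * eps * (src6 * src6 - src6);
          }
        } else {
          wca_pair(r2, m.wca_eps, u, fr);
        }
        ulj += u;
      }
  }
  return List::create(_["U_S"] = us, _["U_L"] = ul, _["U_LJ"] = ulj,
                      _["E"] = us + ul + ulj, _["bad_bond"] = bad_bond);
}

// Contact counts over all frames: C_ij = #(frame, pair) with |ri - rj| < rc.
// [[Rcpp::export(name = ".cpp_contact_counts")]]
NumericMatrix cpp_contact_counts(NumericVector frames, double rc) {
  IntegerVector dim = frames.attr("dim");
  const int n = dim[0], nf = dim[2];
  const double rc2 = rc * rc;
  NumericMatrix C(n, n);
  for (int t = 0; t < nf; ++t) {
    const double *fp = REAL(frames) + (R_xlen_t)n * 3 * t;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double r2 = 0.0;
        for (int c = 0; c < 3; ++c) {
          double d = fp[i + n * c] - fp[j + n * c];
          r2 += d * d;
        }
        if (r2 < rc2) { C(i, j) += 1.0; C(j, i) += 1.0; }
      }
  }
  return C;
}

// Sum and sum of squares of pair distances over frames (for R_ij, dR(s)).
// [[Rcpp::export(name = ".cpp_distance_sums")]]
List cpp_distance_sums(NumericVector frames) {
  IntegerVector dim = frames.attr("dim");
  const int n = dim[0], nf = dim[2];
  NumericMatrix S(n, n), S2(n, n);
  for (int t = 0; t < nf; ++t) {
    const double *fp = REAL(frames) + (R_xlen_t)n * 3 * t;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double r2 = 0.0;
        for (int c = 0; c < 3; ++c) {
          double d = fp[i + n * c] - fp[j + n * c];
          r2 += d * d;
        }
        double r = std::sqrt(r2);
        S(i, j) += r; S(j, i) += r;
        S2(i, j) += r2; S2(j, i) += r2;
      }
  }
  return List::create(_["sum"] = S, _["sumsq"] = S2, _["n_frames"] = nf);
}

// Connected components of the droplet graph: edges where |r_i - r_j| < rad
// and |i - j| > 1. Returns 1-based component labels.
// [[Rcpp::export(name = ".cpp_droplet_components")]]
IntegerVector cpp_droplet_components(NumericMatrix pos, double rad) {
  const int n = pos.nrow();
  const double r2max = rad * rad;
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int i) {
    while (parent[i] != i) { parent[i] = parent[parent[i]]; i = parent[i]; }
    return i;
  };
  // cell hash at cell size = rad
  std::unordered_map<int64_t, std::vector<int> > grid;
  grid.reserve(2 * n);
  const double cell = rad;
  std::vector<int> cx(n), cy(n), cz(n);
  for (int i = 0; i < n; ++i) {
    cx[i] = (int)std::floor(pos(i, 0) / cell);
    cy[i] = (int)std::floor(pos(i, 1) / cell);
    cz[i] = (int)std::floor(pos(i, 2) / cell);
    int64_t key = ((int64_t)(cx[i] + (1 << 20)) << 42) |
                  ((int64_t)(cy[i] + (1 << 20)) << 21) |
                  (int64_t)(cz[i] + (1 << 20));
    grid[key].push_back(i);
  }
  for (int i = 0; i < n; ++i) {
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          int64_t key = ((int64_t)(cx[i] + dx + (1 << 20)) << 42) |
                        ((int64_t)(cy[i] + dy + (1 << 20)) << 21) |
                        (int64_t)(cz[i] + dz + (1 << 20));
          std::unordered_map<int64_t, std::vector<int> >::const_iterator it =
              grid.find(key);
          if (it == grid.end()) continue;
          for (size_t q = 0; q < it->second.size(); ++q) {
            int j = it->second[q];
            if (j <= i || j - i <= 1) continue;
            double r2 = 0.0;
            for (int c = 0; c < 3; ++c) {
              double d = pos(i, c) - pos(j, c);
              r2 += d * d;
            }
            if (r2 < r2max) {
              int ri = find(i), rj = find(j);
              if (ri != rj) parent[ri] = rj;
            }
          }
        }
  }
  IntegerVector out(n);
  std::unordered_map<int, int> relabel;
  for (int i = 0; i < n; ++i) {
    int r = find(i);
    if (!relabel.count(r)) relabel[r] = (int)relabel.size() + 1;
    out[i] = relabel[r];
  }
  return out;
}
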