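// Replica-exchange Metropolis Monte Carlo engine on a C-alpha trace.
//
// The energy model mirrors the R-level internal_energy()/restraint_energy()
// exactly (harmonic bonds, H/E pseudo-angle bias, soft-core repulsion,
// flat-bottom restraints); the test suite asserts equality between recorded
// engine energies and the R recomputation. Randomness comes from one
// xoshiro-style stream per replica (plus one for exchanges), all derived
// from the master seed, so the replica count does not reshuffle streams.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// --- RNG: splitmix64 seeding + xoroshiro128+ streams ---------------------

static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s0, s1;
  void seed(uint64_t master, uint64_t stream) {
    uint64_t x = master * 0x9E3779B97F4A7C15ULL + stream;
    s0 = splitmix64(x);
    s1 = splitmix64(x);
    if (s0 == 0 && s1 == 0) s1 = 1;
  }
  uint64_t next() {
    uint64_t a = s0, b = s1;
    uint64_t r = a + b;
    b ^= a;
    s0 = ((a << 55) | (a >> 9)) ^ b ^ (b << 14);
    s1 = (b << 36) | (b >> 28);
    return r;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int unif_int(int n) { return (int)(unif() * n) % n; }
  void unit_vec(double *v) {
    for (;;) {
      double x = 2 * unif() - 1, y = 2 * unif() - 1, z = 2 * unif() - 1;
      double n2 = x * x + y * y + z * z;
      if (n2 > 1e-12 && n2 <= 1.0) {
        double inv = 1.0 / std::sqrt(n2);
        v[0] = x * inv; v[1] = y * inv; v[2] = z * inv;
        return;
      }
    }
  }
};

// --- model ----------------------------------------------------------------

struct Params {
  double k_bond, k_angle, k_rep, bond_length, clash_dist;
  double p_single, p_crank, p_pivot, max_disp, max_angle;
};

struct Model {
  int n;
  std::vector<double> theta0;           // angle target per center, <0 = none
  std::vector<int> ri, rj;              // restraints, 0-based
  std::vector<double> rdmin, rdmax, rw;
  std::vector<std::vector<int>> radj;   // restraint ids touching each bead
  Params p;

  static double d2(const std::vector<double> &x, int a, int b) {
    double dx = x[3 * a] - x[3 * b];
    double dy = x[3 * a + 1] - x[3 * b + 1];
    double dz = x[3 * a + 2] - x[3 * b + 2];
    return dx * dx + dy * dy + dz * dz;
  }

  double bond_e(const std::vector<double> &x, int k) const {
    double d = std::sqrt(d2(x, k, k + 1)) - p.bond_length;
    return p.k_bond * d * d;
  }

  double angle_e(const std::vector<double> &x, int c) const {
    if (theta0[c] < 0) return 0.0;
    double v1[3], v2[3];
    for (int q = 0; q < 3; ++q) {
      v1[q] = x[3 * (c - 1) + q] - x[3 * c + q];
      v2[q] = x[3 * (c + 1) + q] - x[3 * c + q];
    }
    double dot = v1[0] * v2[0] + v1[1] * v2[1] + v1[2] * v2[2];
    double n1 = std::sqrt(v1[0] * v1[0] + v1[1] * v1[1] + v1[2] * v1[2]);
    double n2 = std::sqrt(v2[0] * v2[0] + v2[1] * v2[1] + v2[2] * v2[2]);
    double ca = dot / (n1 * n2);
    if (ca > 1) ca = 1; else if (ca < -1) ca = -1;
    double dth = std::acos(ca) - theta0[c];
    return p.k_angle * dth * dth;
  }

  double ev_pair(const std::vector<double> &x, int a, int b) const {
    double d = std::sqrt(d2(x, a, b));
    if (d >= p.clash_dist) return 0.0;
    double t = p.clash_dist - d;
    return p.k_rep * t * t;
  }

  double restr_e(const std::vector<double> &x, int r) const {
    double d = std::sqrt(d2(x, ri[r], rj[r]));
    double dev = 0.0;
    if (d > rdmax[r]) dev = d - rdmax[r];
    else if (d < rdmin[r]) dev = rdmin[r] - d;
    return rw[r] * dev * dev;
  }

  double full_energy(const std::vector<double> &x) const {
    double e = 0.0;
    for (int k = 0; k < n - 1; ++k) e += bond_e(x, k);
    for (int c = 1; c < n - 1; ++c) e += angle_e(x, c);
    for (int a = 0; a < n; ++a)
      for (int b = a + 2; b < n; ++b) e += ev_pair(x, a, b);
    for (size_t r = 0; r < ri.size(); ++r) e += restr_e(x, r);
    return e;
  }

  // energy of all terms touching the moved-bead set (m1, optionally m2;
  // moved beads are contiguous when there are two)
  double local_energy(const std::vector<double> &x, int m1, int m2) const {
    double e = 0.0;
    std::vector<char> in(n, 0);
    in[m1] = 1;
    if (m2 >= 0) in[m2] = 1;
    int lo = m1, hi = (m2 >= 0 ? m2 : m1);
    if (lo > hi) std::swap(lo, hi);
    for (int k = std::max(0, lo - 1); k <= std::min(n - 2, hi); ++k)
      e += bond_e(x, k);
    for (int c = std::max(1, lo - 1); c <= std::min(n - 2, hi + 1); ++c)
      e += angle_e(x, c);
    for (int m = lo; m <= hi; ++m) {
      if (!in[m]) continue;
      for (int b = 0; b < n; ++b) {
        if (std::abs(b - m) < 2) continue;
        if (in[b] && b < m) continue;  // count in-set pairs once
        e += ev_pair(x, m < b ? m : b, m < b ? b : m);
      }
      for (int r : radj[m]) {
        int other = (ri[r] == m) ? rj[r] : ri[r];
        if (in[other] && other < m) continue;
        e += restr_e(x, r);
      }
    }
    return e;
  }
};

static void rodrigues(const double *axis, double ang, double *v) {
  double n = std::sqrt(axis[0] * axis[0] + axis[1] * axis[1] +
                       axis[2] * axis[2]);
  double u[3] = {axis[0] / n, axis[1] / n, axis[2] / n};
  double c = std::cos(ang), s = std::sin(ang);
  double dot = u[0] * v[0] + u[1] * v[1] + u[2] * v[2];
  double cr[3] = {u[1] * v[2] - u[2] * v[1],
                  u[2] * v[0] - u[0] * v[2],
                  u[0] * v[1] - u[1] * v[0]};
  for (int q = 0; q < 3; ++q)
    v[q] = v[q] * c + cr[q] * s + u[q] * dot * (1 - c);
}

// propose one local move in place; returns moved beads in m1/m2 (m2 = -1)
static void propose(const Model &M, std::vector<double> &x, Rng &rng,
                    int &m1, int &m2) {
  int n = M.n;
  double ps = M.p.p_single, pc = (n >= 4) ? M.p.p_crank : 0.0,
         pp = M.p.p_pivot;
  double tot = ps + pc + pp;
  double u = rng.unif() * tot;
  m2 = -1;
  if (u < ps) {
    int k = rng.unif_int(n);
    double dir[3];
    rng.unit_vec(dir);
    double r = M.p.max_disp * std::cbrt(rng.unif());
    for (int q = 0; q < 3; ++q) x[3 * k + q] += r * dir[q];
    m1 = k;
  } else if (u < ps + pc) {
    int s = rng.unif_int(n - 3);
    double axis[3];
    for (int q = 0; q < 3; ++q) axis[q] = x[3 * (s + 3) + q] - x[3 * s + q];
    double ang = (2 * rng.unif() - 1) * M.p.max_angle;
    for (int m = s + 1; m <= s + 2; ++m) {
      double v[3];
      for (int q = 0; q < 3; ++q) v[q] = x[3 * m + q] - x[3 * s + q];
      rodrigues(axis, ang, v);
      for (int q = 0; q < 3; ++q) x[3 * m + q] = x[3 * s + q] + v[q];
    }
    m1 = s + 1; m2 = s + 2;
  } else {
    int end = (rng.unif() < 0.5) ? 0 : n - 1;
    int nb = (end == 0) ? 1 : n - 2;
    double axis[3];
    rng.unit_vec(axis);
    double ang = (2 * rng.unif() - 1) * M.p.max_angle;
    double v[3];
    for (int q = 0; q < 3; ++q) v[q] = x[3 * end + q] - x[3 * nb + q];
    rodrigues(axis, ang, v);
    for (int q = 0; q < 3; ++q) x[3 * end + q] = x[3 * nb + q] + v[q];
    m1 = end;
  }
}

// [[Rcpp::export(name = ".remc_engine")]]
List remc_engine(NumericMatrix start, NumericVector theta0,
                 IntegerVector r_i, IntegerVector r_j,
                 NumericVector r_dmin, NumericVector r_dmax,
                 NumericVector r_w, NumericVector ladder,
                 int n_cycles, int record_every, double seed,
                 List params) {
  Model M;
  M.n = start.nrow();
  M.theta0.assign(theta0.begin(), theta0.end());
  M.ri.assign(r_i.begin(), r_i.end());
  M.rj.assign(r_j.begin(), r_j.end());
  M.rdmin.assign(r_dmin.begin(), r_dmin.end());
  M.rdmax.assign(r_dmax.begin(), r_dmax.end());
  M.rw.assign(r_w.begin(), r_w.end());
  M.radj.assign(M.n, {});
  for (size_t r = 0; r < M.ri.size(); ++r) {
    M.radj[M.ri[r]].push_back((int)r);
    M.radj[M.rj[r]].push_back((int)r);
  }
  M.p.k_bond = as<double>(params["k_bond"]);
  M.p.k_angle = as<double>(params["k_angle"]);
  M.p.k_rep = as<double>(params["k_rep"]);
  M.p.bond_length = as<double>(params["bond_length"]);
  M.p.clash_dist = as<double>(params["clash_dist"]);
  M.p.p_single = as<double>(params["p_single"]);
  M.p.p_crank = as<double>(params["p_crank"]);
  M.p.p_pivot = as<double>(params["p_pivot"]);
  M.p.max_disp = as<double>(params["max_disp"]);
  M.p.max_angle = as<double>(params["max_angle"]);

  int R = ladder.size(), n = M.n;
  uint64_t master = (uint64_t)seed;
  std::vector<Rng> rngs(R + 1);
  for (int r = 0; r < R; ++r) rngs[r].seed(master, (uint64_t)r + 1);
  rngs[R].seed(master, 0xE0E0ULL);  // exchange stream

  std::vector<std::vector<double>> X(R);
  std::vector<double> E(R);
  for (int r = 0; r < R; ++r) {
    X[r].assign(start.begin(), start.end());
    // NumericMatrix is column-major n x 3; convert to bead-major
    for (int k = 0; k < n; ++k)
      for (int q = 0; q < 3; ++q) X[r][3 * k + q] = start(k, q);
    E[r] = M.full_energy(X[r]);
  }

  std::vector<long> acc(R, 0), prop(R, 0);
  std::vector<NumericMatrix> snaps;
  std::vector<double> snap_e;
  std::vector<double> rep_e;  // per-replica energies at each record point
  std::vector<int> snap_rep, snap_cycle;
  std::vector<int> swap_cycle, swap_left;
  std::vector<int> swap_acc;

  auto record = [&](int cycle) {
    int best = 0;
    for (int r = 0; r < R; ++r) {
      E[r] = M.full_energy(X[r]);  // fresh recompute: no incremental drift
      rep_e.push_back(E[r]);
      if (E[r] < E[best]) best = r;
    }
    NumericMatrix S(n, 3);
    for (int k = 0; k < n; ++k)
      for (int q = 0; q < 3; ++q) S(k, q) = X[best][3 * k + q];
    snaps.push_back(S);
    snap_e.push_back(E[best]);
    snap_rep.push_back(best + 1);
    snap_cycle.push_back(cycle);
  };

  record(0);
  std::vector<double> xnew;
  for (int cycle = 1; cycle <= n_cycles; ++cycle) {
    for (int r = 0; r < R; ++r) {
      double T = ladder[r];
      for (int mv = 0; mv < n; ++mv) {
        xnew = X[r];
        int m1, m2;
        propose(M, xnew, rngs[r], m1, m2);
        double de = M.local_energy(xnew, m1, m2) -
                    M.local_energy(X[r], m1, m2);
        ++prop[r];
        if (de <= 0 || rngs[r].unif() < std::exp(-de / T)) {
          X[r].swap(xnew);
          E[r] += de;
          ++acc[r];
        }
      }
    }
    // alternating even/odd adjacent exchange phase
    int phase = (cycle % 2 == 1) ? 0 : 1;
    for (int a = phase; a + 1 < R; a += 2) {
      double Ta = ladder[a], Tb = ladder[a + 1];
      double ex = (1.0 / Ta - 1.0 / Tb) * (E[a] - E[a + 1]);
      bool ok = (ex >= 0) || (rngs[R].unif() < std::exp(ex));
      swap_cycle.push_back(cycle);
      swap_left.push_back(a + 1);
      swap_acc.push_back(ok ? 1 : 0);
      if (ok) {
        X[a].swap(X[a + 1]);
        std::swap(E[a], E[a + 1]);
      }
    }
    if (record_every > 0 && cycle % record_every == 0) record(cycle);
  }

  NumericMatrix final_e(1, R);
  for (int r = 0; r < R; ++r) final_e(0, r) = M.full_energy(X[r]);
  List snap_list(snaps.size());
  for (size_t s = 0; s < snaps.size(); ++s) snap_list[s] = snaps[s];
  List finals(R);
  for (int r = 0; r < R; ++r) {
    NumericMatrix S(n, 3);
    for (int k = 0; k < n; ++k)
      for (int q = 0; q < 3; ++q) S(k, q) = X[r][3 * k + q];
    finals[r] = S;
  }
  return List::create(
      _["snapshots"] = snap_list, _["energies"] = wrap(snap_e),
      _["replica"] = wrap(snap_rep), _["cycle"] = wrap(snap_cycle),
      _["accepted"] = wrap(acc), _["proposed"] = wrap(prop),
      _["swap_cycle"] = wrap(swap_cycle), _["swap_lower"] = wrap(swap_left),
      _["swap_accepted"] = wrap(swap_acc),
      _["replica_energies"] = NumericMatrix((int)snaps.size() > 0 ? R : 0,
                                            (int)snaps.size(),
                                            rep_e.begin()),
      _["final_energies"] = final_e,
      _["final_replicas"] = finals);
}

// [[Rcpp::export(name = ".full_energy_cpp")]]
double full_energy_cpp(NumericMatrix coords, NumericVector theta0,
                       IntegerVector r_i, IntegerVector r_j,
                       NumericVector r_dmin, NumericVector r_dmax,
                       NumericVector r_w, List params) {
  Model M;
  M.n = coords.nrow();
  M.theta0.assign(theta0.begin(), theta0.end());
  M.ri.assign(r_i.begin(), r_i.end());
  M.rj.assign(r_j.begin(), r_j.end());
  M.rdmin.assign(r_dmin.begin(), r_dmin.end());
  M.rdmax.assign(r_dmax.begin(), r_dmax.end());
  M.rw.assign(r_w.begin(), r_w.end());
  M.radj.assign(M.n, {});
  M.p.k_bond = as<double>(params["k_bond"]);
  M.p.k_angle = as<double>(params["k_angle"]);
  M.p.k_rep = as<double>(params["k_rep"]);
  M.p.bond_length = as<double>(params["bond_length"]);
  M.p.clash_dist = as<double>(params["clash_dist"]);
  M.p.p_single = M.p.p_crank = M.p.p_pivot = 1;
  M.p.max_disp = M.p.max_angle = 1;
  std::vector<double> x(3 * M.n);
  for (int k = 0; k < M.n; ++k)
    for (int q = 0; q < 3; ++q) x[3 * k + q] = coords(k, q);
  return M.full_energy(x);
}
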