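// Coarse-grained bead-spring MD kernel for collagen fibrils.
//
// Internal units: length angstrom, energy kcal/mol, mass amu.
// The derived time unit is sqrt(amu * A^2 / (kcal/mol)) ~ 48.89 fs.
//
// Force field: piecewise-harmonic breakable backbone/crosslink bonds,
// harmonic bending K_theta*(theta - theta0)^2, and truncated-shifted 12-6
// Lennard-Jones between non-bonded bead pairs (1-2 and 1-3 excluded). A
// bond whose length ever reaches rb is flagged broken and contributes no
// force at any later time.

#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <cmath>
using namespace Rcpp;

struct FF {
  double eps, sigma, kT0, kT1, r0, r1, r1b, rb, c1, c2, ktheta, theta0, rc;
  double ljshift; // energy at cutoff, subtracted so E(rc) = 0
};

static FF unpack_ff(const List& ff) {
  FF p;
  p.eps    = as<double>(ff["eps_lj"]);
  p.sigma  = as<double>(ff["sigma_lj"]);
  p.kT0    = as<double>(ff["kT0"]);
  p.kT1    = as<double>(ff["kT1"]);
  p.r0     = as<double>(ff["r0"]);
  p.r1     = as<double>(ff["r1"]);
  p.r1b    = as<double>(ff["r1_bar"]);
  p.rb     = as<double>(ff["rb"]);
  p.c1     = as<double>(ff["c1"]);
  p.c2     = as<double>(ff["c2"]);
  p.ktheta = as<double>(ff["k_theta"]);
  p.theta0 = as<double>(ff["theta0"]);
  p.rc     = as<double>(ff["lj_cutoff"]);
  double sr6 = std::pow(p.sigma / p.rc, 6.0);
  p.ljshift = 4.0 * p.eps * (sr6 * sr6 - sr6);
  return p;
}

// bond energy and dE/dr; returns false if r >= rb (broken)
static inline bool bond_ef(double r, const FF& p, double& e, double& dedr) {
  if (r >= p.rb) { e = 0.0; dedr = 0.0; return false; }
  if (r < p.r1) {
    e = 0.5 * p.kT0 * (r - p.r0) * (r - p.r0) + p.c1;
    dedr = p.kT0 * (r - p.r0);
  } else {
    e = 0.5 * p.kT1 * (r - p.r1b) * (r - p.r1b) + p.c2;
    dedr = p.kT1 * (r - p.r1b);
  }
  return true;
}

static inline void lj_ef(double r, const FF& p, double& e, double& dedr) {
  double sr6 = std::pow(p.sigma / r, 6.0);
  e = 4.0 * p.eps * (sr6 * sr6 - sr6) - p.ljshift;
  dedr = 4.0 * p.eps * (-12.0 * sr6 * sr6 + 6.0 * sr6) / r;
}

typedef std::unordered_set<long long> PairSet;

static inline long long pkey(int i, int j, int n) {
  if (i > j) std::swap(i, j);
  return (long long)i * (long long)n + (long long)j;
}

static PairSet build_exclusions(const IntegerMatrix& bonds,
                                const IntegerMatrix& angles, int n) {
  PairSet ex;
  for (int b = 0; b < bonds.nrow(); ++b)
    ex.insert(pkey(bonds(b, 0) - 1, bonds(b, 1) - 1, n));
  for (int a = 0; a < angles.nrow(); ++a) {
    ex.insert(pkey(angles(a, 0) - 1, angles(a, 1) - 1, n));
    ex.insert(pkey(angles(a, 1) - 1, angles(a, 2) - 1, n));
    ex.insert(pkey(angles(a, 0) - 1, angles(a, 2) - 1, n));
  }
  return ex;
}

// brute-force neighbour list with skin; pairs stored as flat index pairs
static void rebuild_nlist(const std::vector<double>& x,
                          const std::vector<double>& y,
                          const std::vector<double>& z,
                          const PairSet& excl, double rlist,
                          std::vector<int>& pi, std::vector<int>& pj) {
  int n = (int)x.size();
  pi.clear(); pj.clear();
  double r2 = rlist * rlist;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      if (dx * dx + dy * dy + dz * dz < r2 &&
          excl.find(pkey(i, j, n)) == excl.end()) {
        pi.push_back(i); pj.push_back(j);
      }
    }
}

// accumulate all forces; returns potential energy; adds pair virial zz
static double compute_forces(const std::vector<double>& x,
                             const std::vector<double>& y,
                             const std::vector<double>& z,
                             const IntegerMatrix& bonds,
                             const IntegerMatrix& angles,
                             std::vector<int>& broken,
                             const std::vector<int>& pi,
                             const std::vector<int>& pj,
                             const FF& p,
                             std::vector<double>& fx,
                             std::vector<double>& fy,
                             std::vector<double>& fz,
                             double& virial_zz) {
  int n = (int)x.size();
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  double epot = 0.0;
  virial_zz = 0.0;

  for (int b = 0; b < bonds.nrow(); ++b) {
    if (broken[b]) continue;
    int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
    double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double e, dedr;
    if (!bond_ef(r, p, e, dedr)) { broken[b] = 1; continue; }
    epot += e;
    double fr = -dedr / r; // force on i along (ri - rj)
    fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
    fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
    virial_zz += fr * dz * dz;
  }

  double rc2 = p.rc * p.rc;
  for (size_t k = 0; k < pi.size(); ++k) {
    int i = pi[k], j = pj[k];
    double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= rc2) continue;
    double r = std::sqrt(r2);
    double e, dedr;
    lj_ef(r, p, e, dedr);
    epot += e;
    double fr = -dedr / r;
    fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
    fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
    virial_zz += fr * dz * dz;
  }

  for (int a = 0; a < angles.nrow(); ++a) {
    int i = angles(a, 0) - 1, j = angles(a, 1) - 1, k = angles(a, 2) - 1;
    double ax = x[i] - x[j], ay = y[i] - y[j], az = z[i] - z[j];
    double bx2 = x[k] - x[j], by2 = y[k] - y[j], bz2 = z[k] - z[j];
    double ra = std::sqrt(ax * ax + ay * ay + az * az);
    double rb2 = std::sqrt(bx2 * bx2 + by2 * by2 + bz2 * bz2);
    double cosv = (ax * bx2 + ay * by2 + az * bz2) / (ra * rb2);
    if (cosv > 1.0) cosv = 1.0;
    if (cosv < -1.0) cosv = -1.0;
    double th = std::acos(cosv);
    epot += p.ktheta * (th - p.theta0) * (th - p.theta0);
    double dEdth = 2.0 * p.ktheta * (th - p.theta0);
    double sinv = std::sqrt(1.0 - cosv * cosv);
    if (sinv < 1e-8) sinv = 1e-8;
    // dcos/dri and dcos/drk, chain rule through theta = acos(cos)
    double coef = dEdth / sinv; // -dE/dcos = dEdth / sin
    double dix = (bx2 / (ra * rb2) - cosv * ax / (ra * ra));
    double diy = (by2 / (ra * rb2) - cosv * ay / (ra * ra));
    double diz = (bz2 / (ra * rb2) - cosv * az / (ra * ra));
    double dkx = (ax / (ra * rb2) - cosv * bx2 / (rb2 * rb2));
    double dky = (ay / (ra * rb2) - cosv * by2 / (rb2 * rb2));
    double dkz = (az / (ra * rb2) - cosv * bz2 / (rb2 * rb2));
    // force = -dE/dr = -dE/dtheta * dtheta/dcos * dcos/dr = coef * dcos/dr
    fx[i] += coef * dix; fy[i] += coef * diy; fz[i] += coef * diz;
    fx[k] += coef * dkx; fy[k] += coef * dky; fz[k] += coef * dkz;
    fx[j] -= coef * (dix + dkx);
    fy[j] -= coef * (diy + dky);
    fz[j] -= coef * (diz + dkz);
  }
  return epot;
}

// [[Rcpp::export]]
List md_energy_forces(NumericMatrix pos, IntegerMatrix bonds,
                      IntegerMatrix angles, IntegerVector broken_in,
                      List ff) {
  FF p = unpack_ff(ff);
  int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n), fx(n), fy(n), fz(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i,0); y[i] = pos(i,1); z[i] = pos(i,2); }
  std::vector<int> broken(broken_in.begin(), broken_in.end());
  PairSet excl = build_exclusions(bonds, angles, n);
  std::vector<int> pi, pj;
  rebuild_nlist(x, y, z, excl, p.rc, pi, pj);
  double vzz;
  double epot = compute_forces(x, y, z, bonds, angles, broken, pi, pj, p,
                               fx, fy, fz, vzz);
  NumericMatrix F(n, 3);
  for (int i = 0; i < n; ++i) { F(i,0) = fx[i]; F(i,1) = fy[i]; F(i,2) = fz[i]; }
  return List::create(_["potential"] = epot, _["forces"] = F,
                      _["broken"] = IntegerVector(broken.begin(), broken.end()),
                      _["virial_zz"] = vzz);
}

// Velocity-Verlet integrator with optional Langevin thermostat and
// prescribed-velocity grip groups.
//
// mode: 0 = free, 1 = frozen (zero velocity), 2 = moving grip
// grip_vel: 3-vector applied to mode-2 beads
// Forces accumulated on mode>0 beads over each sample window give the
// boundary reaction used for the engineering stress.
//
// [[Rcpp::export]]
List md_run(NumericMatrix pos, NumericMatrix vel, NumericVector mass,
            IntegerMatrix bonds, IntegerMatrix angles,
            IntegerVector broken_in, List ff, double dt, int n_steps,
            int langevin, double gamma, double kT, IntegerVector mode,
            NumericVector grip_vel, int sample_every, int nlist_every,
            double skin) {
  FF p = unpack_ff(ff);
  int n = pos.nrow();
  NumericMatrix posc = clone(pos), velc = clone(vel);
  std::vector<double> x(n), y(n), z(n), vx(n), vy(n), vz(n),
      fx(n), fy(n), fz(n);
  for (int i = 0; i < n; ++i) {
    x[i] = posc(i,0); y[i] = posc(i,1); z[i] = posc(i,2);
    vx[i] = velc(i,0); vy[i] = velc(i,1); vz[i] = velc(i,2);
  }
  std::vector<int> broken(broken_in.begin(), broken_in.end());
  PairSet excl = build_exclusions(bonds, angles, n);
  std::vector<int> pi, pj;
  rebuild_nlist(x, y, z, excl, p.rc + skin, pi, pj);

  int n_samples = n_steps / sample_every;
  NumericVector s_time(n_samples), s_epot(n_samples), s_ekin(n_samples),
      s_gripfz(n_samples), s_virzz(n_samples), s_gripz(n_samples);

  double vzz;
  double epot = compute_forces(x, y, z, bonds, angles, broken, pi, pj, p,
                               fx, fy, fz, vzz);
  double grip_acc = 0.0, vir_acc = 0.0;
  int acc_n = 0;
  // R RNG state is handled by the generated wrapper (reproducible under
  // set.seed() in the caller)

  for (int step = 1; step <= n_steps; ++step) {
    // half kick + drift
    for (int i = 0; i < n; ++i) {
      if (mode[i] == 0) {
        double h = 0.5 * dt / mass[i];
        vx[i] += h * fx[i]; vy[i] += h * fy[i]; vz[i] += h * fz[i];
        x[i] += dt * vx[i]; y[i] += dt * vy[i]; z[i] += dt * vz[i];
      } else if (mode[i] == 2) {
        x[i] += dt * grip_vel[0]; y[i] += dt * grip_vel[1];
        z[i] += dt * grip_vel[2];
      }
    }
    if (step % nlist_every == 0)
      rebuild_nlist(x, y, z, excl, p.rc + skin, pi, pj);
    epot = compute_forces(x, y, z, bonds, angles, broken, pi, pj, p,
                          fx, fy, fz, vzz);
    if (langevin) {
      // Langevin as post-force modification (BBK-style)
      double pref = std::sqrt(2.0 * gamma * kT / dt);
      for (int i = 0; i < n; ++i) {
        if (mode[i] != 0) continue;
        double sm = std::sqrt(mass[i]);
        fx[i] += -gamma * mass[i] * vx[i] + pref * sm * R::norm_rand();
        fy[i] += -gamma * mass[i] * vy[i] + pref * sm * R::norm_rand();
        fz[i] += -gamma * mass[i] * vz[i] + pref * sm * R::norm_rand();
      }
    }
    double ekin = 0.0;
    for (int i = 0; i < n; ++i) {
      if (mode[i] == 0) {
        double h = 0.5 * dt / mass[i];
        vx[i] += h * fx[i]; vy[i] += h * fy[i]; vz[i] += h * fz[i];
      }
      ekin += 0.5 * mass[i] * (vx[i]*vx[i] + vy[i]*vy[i] + vz[i]*vz[i]);
    }
    // reaction force on the moving grip (mode 2), z component
    double gfz = 0.0;
    for (int i = 0; i < n; ++i) if (mode[i] == 2) gfz += fz[i];
    grip_acc += gfz; vir_acc += vzz; acc_n++;

    if (step % sample_every == 0) {
      int s = step / sample_every - 1;
      s_time[s] = step * dt;
      s_epot[s] = epot;
      s_ekin[s] = ekin;
      s_gripfz[s] = grip_acc / acc_n;
      s_virzz[s] = vir_acc / acc_n;
      double gz = 0.0; int ng = 0;
      for (int i = 0; i < n; ++i) if (mode[i] == 2) { gz += z[i]; ng++; }
      s_gripz[s] = ng ? gz / ng : NA_REAL;
      grip_acc = 0.0; vir_acc = 0.0; acc_n = 0;
      if (!R_finite(epot)) stop("numerical blow-up: non-finite energy at step %d", step);
    }
  }
  for (int i = 0; i < n; ++i) {
    posc(i,0) = x[i]; posc(i,1) = y[i]; posc(i,2) = z[i];
    velc(i,0) = vx[i]; velc(i,1) = vy[i]; velc(i,2) = vz[i];
  }
  return List::create(_["pos"] = posc, _["vel"] = velc,
                      _["broken"] = IntegerVector(broken.begin(), broken.end()),
                      _["time"] = s_time, _["epot"] = s_epot,
                      _["ekin"] = s_ekin, _["grip_fz"] = s_gripfz,
                      _["grip_z"] = s_gripz, _["virial_zz"] = s_virzz);
}
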