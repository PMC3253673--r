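// Core simulator: bead-spring filaments with curvature elasticity and WCA
// excluded volume, two-headed Hookean motor springs with kinetic Monte Carlo
// attachment / stepping / detachment, quasi-2D confinement between planar
// z-walls and an elastic side wall that equilibrates against an external
// pressure by Metropolis Monte Carlo.
//
// Units: energies in kBT, lengths in the bond length b unless scaled by the
// params, time in gamma*b^2/kBT.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: xoshiro256++ seeded via splitmix64; independent streams per subsystem
// so that e.g. adding wall moves does not perturb the thermal noise sequence.
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

struct RngStream {
  uint64_t s[4];
  bool have_cached = false;
  double cached = 0.0;

  void seed(uint64_t sd) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(sd);
    have_cached = false;
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1)
  double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double unif_ab(double a, double b) { return a + (b - a) * unif(); }
  int unif_int(int n) { // 0..n-1
    return (int)(unif() * n) % n;
  }
  double norm() {
    if (have_cached) { have_cached = false; return cached; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), th = 2.0 * M_PI * u2;
    cached = r * std::sin(th);
    have_cached = true;
    return r * std::cos(th);
  }
};

// ---------------------------------------------------------------------------
// Parameters
// ---------------------------------------------------------------------------

struct SimParams {
  int N = 0, M = 0;
  double b = 1.0, sigma = 1.0, eps = 5.0;
  double k_bond = 100.0, kappa = 200.0, k_motor = 1.0, attach_range = 0.0;
  double kA = 0.0, kD = 0.0, kM = 0.0, kE = 0.0;
  double gamma = 1.0, P = 0.0, Z = 5.0, kT = 1.0;
  double c_stretch = 0.5, c_bend = 1000.0;
  double dt = 5e-4;
  double max_disp = 0.25;
  int kinetics_interval = 10, wall_interval = 10;
  double delta_wall = 0.1;
  bool fixed_volume = false;
  double fixed_radius = -1.0;
  double wall_l0 = 0.0, wall_kappa0 = 0.0;
};

static SimParams parse_params(const List &par) {
  SimParams p;
  p.N = as<int>(par["N"]); p.M = as<int>(par["M"]);
  p.b = as<double>(par["b"]); p.sigma = as<double>(par["sigma"]);
  p.eps = as<double>(par["eps"]);
  p.k_bond = as<double>(par["k_bond"]); p.kappa = as<double>(par["kappa"]);
  p.k_motor = as<double>(par["k_motor"]);
  p.attach_range = as<double>(par["attach_range"]);
  p.kA = as<double>(par["k_A"]); p.kD = as<double>(par["k_D"]);
  p.kM = as<double>(par["k_M"]); p.kE = as<double>(par["k_E"]);
  p.gamma = as<double>(par["gamma"]); p.P = as<double>(par["P"]);
  p.Z = as<double>(par["Z"]); p.kT = as<double>(par["kT"]);
  p.c_stretch = as<double>(par["c_stretch"]);
  p.c_bend = as<double>(par["c_bend"]);
  p.dt = as<double>(par["dt"]);
  p.max_disp = as<double>(par["max_disp"]);
  p.kinetics_interval = as<int>(par["kinetics_interval"]);
  p.wall_interval = as<int>(par["wall_interval"]);
  p.delta_wall = as<double>(par["delta_wall"]);
  p.fixed_volume = as<bool>(par["fixed_volume"]);
  p.fixed_radius = as<double>(par["fixed_radius"]);
  p.wall_l0 = as<double>(par["wall_l0"]);
  p.wall_kappa0 = as<double>(par["wall_kappa0"]);
  return p;
}

// ---------------------------------------------------------------------------
// WCA (truncated-shifted repulsive Lennard-Jones)
// ---------------------------------------------------------------------------

static inline double wca_cut(double sigma) { return std::pow(2.0, 1.0 / 6.0) * sigma; }

static inline double wca_energy(double r, double sigma, double eps) {
  if (r >= wca_cut(sigma)) return 0.0;
  double sr2 = (sigma / r) * (sigma / r);
  double sr6 = sr2 * sr2 * sr2;
  return 4.0 * eps * (sr6 * sr6 - sr6) + eps;
}

// magnitude of -dU/dr (>0 means repulsive, pointing from wall/partner)
static inline double wca_force(double r, double sigma, double eps) {
  if (r >= wca_cut(sigma)) return 0.0;
  double sr2 = (sigma / r) * (sigma / r);
  double sr6 = sr2 * sr2 * sr2;
  return 24.0 * eps * (2.0 * sr6 * sr6 - sr6) / r;
}

// 2D distance from point p to segment a-b; writes nearest point q
static inline double pt_seg_dist(double px, double py, double ax, double ay,
                                 double bx, double by, double &qx, double &qy) {
  double dx = bx - ax, dy = by - ay;
  double len2 = dx * dx + dy * dy;
  double t = 0.0;
  if (len2 > 0.0) {
    t = ((px - ax) * dx + (py - ay) * dy) / len2;
    t = std::max(0.0, std::min(1.0, t));
  }
  qx = ax + t * dx; qy = ay + t * dy;
  double ex = px - qx, ey = py - qy;
  return std::sqrt(ex * ex + ey * ey);
}

// ---------------------------------------------------------------------------
// Simulation object
// ---------------------------------------------------------------------------

struct EnergyTerms {
  double bond = 0, bend = 0, ev = 0, zwall = 0, sidewall = 0, motor = 0;
};

struct GelSim {
  SimParams p;
  int nm = 0; // total monomers
  std::vector<double> x, y, z;       // coordinates
  std::vector<double> fx, fy, fz;    // forces
  std::vector<std::array<int, 4>> motors; // fil_a, mon_a, fil_b, mon_b (0-based)
  std::vector<double> wx, wy;        // wall node coordinates
  double orient = 1.0;               // sign of initial polygon area
  double time = 0.0;
  long step_count = 0;
  RngStream rng_bd, rng_kin, rng_wall;

  // neighbour bookkeeping
  std::vector<std::pair<int, int>> pairs; // candidate EV/attachment pairs
  std::vector<int> wall_near;             // monomers near the side wall
  int list_age = 1 << 30;                 // force rebuild on first use
  double skin = 0.5;

  int fil_of(int i) const { return i / p.M; }
  int mon_of(int i) const { return i % p.M; }
  int gidx(int f, int m) const { return f * p.M + m; }

  bool has_zwalls() const { return std::isfinite(p.Z) && p.Z > 0; }
  bool has_polygon() const { return !p.fixed_volume && wx.size() >= 3; }
  bool has_circle() const {
    return p.fixed_volume && std::isfinite(p.fixed_radius) && p.fixed_radius > 0;
  }

  // --- neighbour list ---------------------------------------------------
  void build_lists() {
    double rc = std::max(wca_cut(p.sigma), p.attach_range) + skin;
    pairs.clear();
    if (nm > 1) {
      double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0],
             zmin = z[0], zmax = z[0];
      for (int i = 1; i < nm; ++i) {
        xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
        ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
        zmin = std::min(zmin, z[i]); zmax = std::max(zmax, z[i]);
      }
      int ncx = std::max(1, (int)((xmax - xmin) / rc));
      int ncy = std::max(1, (int)((ymax - ymin) / rc));
      int ncz = std::max(1, (int)((zmax - zmin) / rc));
      ncx = std::min(ncx, 128); ncy = std::min(ncy, 128); ncz = std::min(ncz, 128);
      double cx = (xmax - xmin) / ncx + 1e-12, cy = (ymax - ymin) / ncy + 1e-12,
             cz = (zmax - zmin) / ncz + 1e-12;
      int ncell = ncx * ncy * ncz;
      std::vector<int> head(ncell, -1), nxt(nm, -1);
      std::vector<int> ci(nm), cj(nm), ck(nm);
      for (int i = 0; i < nm; ++i) {
        int a = std::min(ncx - 1, (int)((x[i] - xmin) / cx));
        int b2 = std::min(ncy - 1, (int)((y[i] - ymin) / cy));
        int c = std::min(ncz - 1, (int)((z[i] - zmin) / cz));
        ci[i] = a; cj[i] = b2; ck[i] = c;
        int cell = (c * ncy + b2) * ncx + a;
        nxt[i] = head[cell]; head[cell] = i;
      }
      double rc2 = rc * rc;
      for (int i = 0; i < nm; ++i) {
        for (int dc = -1; dc <= 1; ++dc) {
          int c = ck[i] + dc; if (c < 0 || c >= ncz) continue;
          for (int db = -1; db <= 1; ++db) {
            int b2 = cj[i] + db; if (b2 < 0 || b2 >= ncy) continue;
            for (int da = -1; da <= 1; ++da) {
              int a = ci[i] + da; if (a < 0 || a >= ncx) continue;
              int cell = (c * ncy + b2) * ncx + a;
              for (int j = head[cell]; j >= 0; j = nxt[j]) {
                if (j <= i) continue;
                // exclude directly bonded neighbours only
                if (fil_of(i) == fil_of(j) && std::abs(mon_of(i) - mon_of(j)) == 1)
                  continue;
                double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
                if (dx * dx + dy * dy + dz * dz < rc2)
                  pairs.push_back(std::make_pair(i, j));
              }
            }
          }
        }
      }
    }
    // monomers within reach of the side wall
    wall_near.clear();
    if (has_polygon()) {
      double cxw = 0, cyw = 0;
      int nw = (int)wx.size();
      for (int k = 0; k < nw; ++k) { cxw += wx[k]; cyw += wy[k]; }
      cxw /= nw; cyw /= nw;
      double rin = 1e300;
      for (int k = 0; k < nw; ++k) {
        double dx = wx[k] - cxw, dy = wy[k] - cyw;
        rin = std::min(rin, std::sqrt(dx * dx + dy * dy));
      }
      double thr = rin - (wca_cut(p.sigma) + skin + p.wall_l0);
      for (int i = 0; i < nm; ++i) {
        double dx = x[i] - cxw, dy = y[i] - cyw;
        if (std::sqrt(dx * dx + dy * dy) > thr) wall_near.push_back(i);
      }
    } else if (has_circle()) {
      double thr = p.fixed_radius - (wca_cut(p.sigma) + skin);
      for (int i = 0; i < nm; ++i)
        if (std::sqrt(x[i] * x[i] + y[i] * y[i]) > thr) wall_near.push_back(i);
    }
    list_age = 0;
  }

  double nearest_wall_dist(double px, double py, double &qx, double &qy) const {
    int nw = (int)wx.size();
    double best = 1e300; qx = px; qy = py;
    for (int k = 0; k < nw; ++k) {
      int k2 = (k + 1) % nw;
      double tx, ty;
      double d = pt_seg_dist(px, py, wx[k], wy[k], wx[k2], wy[k2], tx, ty);
      if (d < best) { best = d; qx = tx; qy = ty; }
    }
    return best;
  }

  // --- forces and energies ----------------------------------------------
  // brute = evaluate all monomer pairs (reference path used by tests)
  EnergyTerms compute_forces(bool use_nlist) {
    EnergyTerms e;
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);

    // bonds + bending per filament
    for (int f = 0; f < p.N; ++f) {
      int o = f * p.M;
      // bonds
      for (int m = 0; m + 1 < p.M; ++m) {
        int i = o + m, j = i + 1;
        double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (r < 1e-10)
          stop("degenerate geometry: coincident bonded monomers (filament %d, monomer %d)",
               f + 1, m + 1);
        double dr = r - p.b;
        e.bond += 0.5 * p.k_bond * dr * dr;
        double fmag = -p.k_bond * dr / r; // along (j - i), applied to j
        fx[j] += fmag * dx; fy[j] += fmag * dy; fz[j] += fmag * dz;
        fx[i] -= fmag * dx; fy[i] -= fmag * dy; fz[i] -= fmag * dz;
      }
      // bending: U = (kappa/b) * sum_j (1 - cos theta_j)
      double kb = p.kappa / p.b;
      for (int m = 0; m + 2 < p.M; ++m) {
        int i = o + m, j = i + 1, k = i + 2;
        double ux = x[j] - x[i], uy = y[j] - y[i], uz = z[j] - z[i];
        double vx = x[k] - x[j], vy = y[k] - y[j], vz = z[k] - z[j];
        double lu = std::sqrt(ux * ux + uy * uy + uz * uz);
        double lv = std::sqrt(vx * vx + vy * vy + vz * vz);
        if (lu < 1e-10 || lv < 1e-10)
          stop("degenerate geometry: zero bond vector in bending term");
        double inv = 1.0 / (lu * lv);
        double c = (ux * vx + uy * vy + uz * vz) * inv;
        e.bend += kb * (1.0 - c);
        // d c / d u and d c / d v
        double dcux = vx * inv - c * ux / (lu * lu);
        double dcuy = vy * inv - c * uy / (lu * lu);
        double dcuz = vz * inv - c * uz / (lu * lu);
        double dcvx = ux * inv - c * vx / (lv * lv);
        double dcvy = uy * inv - c * vy / (lv * lv);
        double dcvz = uz * inv - c * vz / (lv * lv);
        // F = -dU/dr = +kb * dc/dr
        fx[i] -= kb * dcux; fy[i] -= kb * dcuy; fz[i] -= kb * dcuz;
        fx[j] += kb * (dcux - dcvx); fy[j] += kb * (dcuy - dcvy); fz[j] += kb * (dcuz - dcvz);
        fx[k] += kb * dcvx; fy[k] += kb * dcvy; fz[k] += kb * dcvz;
      }
    }

    // excluded volume
    double rc = wca_cut(p.sigma), rc2 = rc * rc;
    if (use_nlist) {
      if (list_age > p.kinetics_interval) build_lists();
      for (size_t q = 0; q < pairs.size(); ++q) {
        int i = pairs[q].first, j = pairs[q].second;
        double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 >= rc2) continue;
        double r = std::sqrt(r2);
        e.ev += wca_energy(r, p.sigma, p.eps);
        double fm = wca_force(r, p.sigma, p.eps) / r;
        fx[i] += fm * dx; fy[i] += fm * dy; fz[i] += fm * dz;
        fx[j] -= fm * dx; fy[j] -= fm * dy; fz[j] -= fm * dz;
      }
    } else {
      for (int i = 0; i < nm; ++i) {
        for (int j = i + 1; j < nm; ++j) {
          if (fil_of(i) == fil_of(j) && std::abs(mon_of(i) - mon_of(j)) == 1)
            continue;
          double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
          double r2 = dx * dx + dy * dy + dz * dz;
          if (r2 >= rc2) continue;
          double r = std::sqrt(r2);
          e.ev += wca_energy(r, p.sigma, p.eps);
          double fm = wca_force(r, p.sigma, p.eps) / r;
          fx[i] += fm * dx; fy[i] += fm * dy; fz[i] += fm * dz;
          fx[j] -= fm * dx; fy[j] -= fm * dy; fz[j] -= fm * dz;
        }
      }
    }

    // confining planes at z = 0 and z = Z
    if (has_zwalls()) {
      for (int i = 0; i < nm; ++i) {
        double d0 = z[i];
        if (d0 > 0 && d0 < rc) {
          e.zwall += wca_energy(d0, p.sigma, p.eps);
          fz[i] += wca_force(d0, p.sigma, p.eps);
        }
        double d1 = p.Z - z[i];
        if (d1 > 0 && d1 < rc) {
          e.zwall += wca_energy(d1, p.sigma, p.eps);
          fz[i] -= wca_force(d1, p.sigma, p.eps);
        }
      }
    }

    // side wall
    if (has_polygon()) {
      const std::vector<int> *cand = use_nlist ? &wall_near : nullptr;
      int ncand = use_nlist ? (int)wall_near.size() : nm;
      for (int q = 0; q < ncand; ++q) {
        int i = cand ? (*cand)[q] : q;
        double qx, qy;
        double d = nearest_wall_dist(x[i], y[i], qx, qy);
        if (d <= 0 || d >= rc) continue;
        e.sidewall += wca_energy(d, p.sigma, p.eps);
        double fm = wca_force(d, p.sigma, p.eps) / d;
        fx[i] += fm * (x[i] - qx);
        fy[i] += fm * (y[i] - qy);
      }
    } else if (has_circle()) {
      const std::vector<int> *cand = use_nlist ? &wall_near : nullptr;
      int ncand = use_nlist ? (int)wall_near.size() : nm;
      for (int q = 0; q < ncand; ++q) {
        int i = cand ? (*cand)[q] : q;
        double rho = std::sqrt(x[i] * x[i] + y[i] * y[i]);
        double d = std::fabs(p.fixed_radius - rho);
        if (d >= rc || rho < 1e-12) continue;
        e.sidewall += wca_energy(d, p.sigma, p.eps);
        double fm = wca_force(d, p.sigma, p.eps);
        double s = (rho < p.fixed_radius) ? -1.0 : 1.0; // push away from wall
        fx[i] += s * fm * x[i] / rho;
        fy[i] += s * fm * y[i] / rho;
      }
    }

    // motor springs (zero rest length)
    for (size_t q = 0; q < motors.size(); ++q) {
      int ia = gidx(motors[q][0], motors[q][1]);
      int ib = gidx(motors[q][2], motors[q][3]);
      double dx = x[ia] - x[ib], dy = y[ia] - y[ib], dz = z[ia] - z[ib];
      e.motor += 0.5 * p.k_motor * (dx * dx + dy * dy + dz * dz);
      fx[ia] -= p.k_motor * dx; fy[ia] -= p.k_motor * dy; fz[ia] -= p.k_motor * dz;
      fx[ib] += p.k_motor * dx; fy[ib] += p.k_motor * dy; fz[ib] += p.k_motor * dz;
    }
    return e;
  }

  // unit tangent at monomer i (mean of adjacent bond directions); returns
  // false when degenerate (fall back to isotropic drag)
  bool tangent(int i, double &tx, double &ty, double &tz) const {
    int m = mon_of(i), o = fil_of(i) * p.M;
    double ax = 0, ay = 0, az = 0;
    if (m > 0) {
      int j = o + m - 1;
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      double l = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (l > 1e-10) { ax += dx / l; ay += dy / l; az += dz / l; }
    }
    if (m + 1 < p.M) {
      int j = o + m + 1;
      double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
      double l = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (l > 1e-10) { ax += dx / l; ay += dy / l; az += dz / l; }
    }
    double l = std::sqrt(ax * ax + ay * ay + az * az);
    if (l < 1e-10) return false;
    tx = ax / l; ty = ay / l; tz = az / l;
    return true;
  }

  void bd_step() {
    if (list_age >= p.kinetics_interval) build_lists();
    compute_forces(true);
    double dt = p.dt, g = p.gamma;
    double spar = std::sqrt(2.0 * p.kT * dt / g);
    double sperp = std::sqrt(p.kT * dt / g);
    for (int i = 0; i < nm; ++i) {
      double tx, ty, tz;
      double dxm, dym, dzm;
      double g1 = rng_bd.norm(), g2 = rng_bd.norm(), g3 = rng_bd.norm();
      if (tangent(i, tx, ty, tz)) {
        double fpar = fx[i] * tx + fy[i] * ty + fz[i] * tz;
        dxm = dt * (fpar * tx / g + (fx[i] - fpar * tx) / (2.0 * g));
        dym = dt * (fpar * ty / g + (fy[i] - fpar * ty) / (2.0 * g));
        dzm = dt * (fpar * tz / g + (fz[i] - fpar * tz) / (2.0 * g));
        double gpar = g1 * tx + g2 * ty + g3 * tz;
        dxm += spar * gpar * tx + sperp * (g1 - gpar * tx);
        dym += spar * gpar * ty + sperp * (g2 - gpar * ty);
        dzm += spar * gpar * tz + sperp * (g3 - gpar * tz);
      } else {
        dxm = dt * fx[i] / (2.0 * g) + sperp * g1;
        dym = dt * fy[i] / (2.0 * g) + sperp * g2;
        dzm = dt * fz[i] / (2.0 * g) + sperp * g3;
      }
      if (!std::isfinite(dxm) || !std::isfinite(dym) || !std::isfinite(dzm))
        stop("integration blow-up at monomer %d (filament %d) at t = %g",
             mon_of(i) + 1, fil_of(i) + 1, time);
      // clamp the step length: steep WCA overlaps (e.g. in a crowded
      // initial state) must relax over several steps, not overshoot
      if (p.max_disp > 0) {
        double dn = std::sqrt(dxm * dxm + dym * dym + dzm * dzm);
        if (dn > p.max_disp) {
          double sc = p.max_disp / dn;
          dxm *= sc; dym *= sc; dzm *= sc;
        }
      }
      x[i] += dxm; y[i] += dym; z[i] += dzm;
    }
    time += dt;
    ++step_count;
    ++list_age;
  }

  // --- motor kinetics ----------------------------------------------------
  double motor_energy(int ia, int ib) const {
    double dx = x[ia] - x[ib], dy = y[ia] - y[ib], dz = z[ia] - z[ib];
    return 0.5 * p.k_motor * (dx * dx + dy * dy + dz * dz);
  }

  List kinetics_sweep(bool do_attach = true, bool do_move = true,
                      bool do_detach = true) {
    double dtk = p.kinetics_interval * p.dt;
    int n_att = 0, n_mov = 0, n_det = 0, n_end_det = 0;
    if (list_age > 0) build_lists();

    // attachments: every monomer pair on different filaments within range
    if (do_attach && p.kA > 0) {
      double p_att = 1.0 - std::exp(-p.kA * dtk);
      double ar2 = p.attach_range * p.attach_range;
      for (size_t q = 0; q < pairs.size(); ++q) {
        int i = pairs[q].first, j = pairs[q].second;
        if (fil_of(i) == fil_of(j)) continue;
        double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
        if (dx * dx + dy * dy + dz * dz >= ar2) continue;
        if (rng_kin.unif() < p_att) {
          std::array<int, 4> mo = {fil_of(i), mon_of(i), fil_of(j), mon_of(j)};
          motors.push_back(mo);
          ++n_att;
        }
      }
    }

    // moves: heads in random order, stepping toward the [+]-end (monomer M-1)
    if (do_move && p.kM > 0 && !motors.empty()) {
      int nh = 2 * (int)motors.size();
      std::vector<int> order(nh);
      for (int h = 0; h < nh; ++h) order[h] = h;
      for (int h = nh - 1; h > 0; --h)
        std::swap(order[h], order[rng_kin.unif_int(h + 1)]);
      for (int h = 0; h < nh; ++h) {
        int mi = order[h] / 2, side = order[h] % 2;
        int fi = motors[mi][2 * side], mo = motors[mi][2 * side + 1];
        if (mo >= p.M - 1) continue; // heads at the [+]-end dwell
        int other = gidx(motors[mi][2 * (1 - side)], motors[mi][2 * (1 - side) + 1]);
        double e0 = motor_energy(gidx(fi, mo), other);
        double e1 = motor_energy(gidx(fi, mo + 1), other);
        double pr = p.kM * dtk * std::exp(-(e1 - e0) / p.kT);
        if (pr > 1.0) pr = 1.0;
        if (rng_kin.unif() < pr) {
          motors[mi][2 * side + 1] = mo + 1;
          ++n_mov;
        }
      }
    }

    // detachments: each head independently; k_E replaces k_D at the [+]-end;
    // either head firing removes the whole motor
    if (do_detach && (p.kD > 0 || p.kE > 0)) {
      double p_int = 1.0 - std::exp(-p.kD * dtk);
      double p_end = 1.0 - std::exp(-p.kE * dtk);
      for (int mi = (int)motors.size() - 1; mi >= 0; --mi) {
        bool gone = false, at_end_fired = false;
        for (int side = 0; side < 2; ++side) {
          bool at_end = motors[mi][2 * side + 1] >= p.M - 1;
          double pd = at_end ? p_end : p_int;
          if (rng_kin.unif() < pd) {
            gone = true;
            if (at_end) at_end_fired = true;
          }
        }
        if (gone) {
          motors.erase(motors.begin() + mi);
          ++n_det;
          if (at_end_fired) ++n_end_det;
        }
      }
    }

    int n_plus = 0;
    for (size_t q = 0; q < motors.size(); ++q)
      if (motors[q][1] >= p.M - 1 || motors[q][3] >= p.M - 1) ++n_plus;

    return List::create(_["n_attached"] = n_att, _["n_moved"] = n_mov,
                        _["n_detached"] = n_det, _["n_end_detached"] = n_end_det,
                        _["n_mot"] = (int)motors.size(), _["n_mot_plus"] = n_plus);
  }

  // --- wall Monte Carlo ---------------------------------------------------
  double signed_area() const {
    int nw = (int)wx.size();
    double a = 0;
    for (int k = 0; k < nw; ++k) {
      int k2 = (k + 1) % nw;
      a += wx[k] * wy[k2] - wx[k2] * wy[k];
    }
    return 0.5 * a;
  }

  double turn_angle(int k) const {
    int nw = (int)wx.size();
    int km = (k + nw - 1) % nw, kp = (k + 1) % nw;
    double ux = wx[k] - wx[km], uy = wy[k] - wy[km];
    double vx = wx[kp] - wx[k], vy = wy[kp] - wy[k];
    return std::atan2(ux * vy - uy * vx, ux * vx + uy * vy);
  }

  // elastic energy of node pair/triplet terms touching node k
  double wall_local_energy(int k) const {
    int nw = (int)wx.size();
    double e = 0;
    for (int s = -1; s <= 0; ++s) { // segments (k-1,k) and (k,k+1)
      int a = (k + s + nw) % nw, b2 = (a + 1) % nw;
      double dx = wx[b2] - wx[a], dy = wy[b2] - wy[a];
      double dl = std::sqrt(dx * dx + dy * dy) - p.wall_l0;
      e += p.c_stretch * p.kT * p.Z * dl * dl / std::pow(p.wall_l0, 3);
    }
    for (int s = -1; s <= 1; ++s) { // triplets centred on k-1, k, k+1
      int c = (k + s + nw) % nw;
      double dk = turn_angle(c) / p.wall_l0 - p.wall_kappa0;
      e += p.c_bend * p.kT * p.wall_l0 * p.Z * dk * dk;
    }
    return e;
  }

  // side-wall LJ energy of the given monomers against the full polygon
  double wall_monomer_energy(const std::vector<int> &cand) const {
    double e = 0, rc = wca_cut(p.sigma);
    for (size_t q = 0; q < cand.size(); ++q) {
      int i = cand[q];
      double qx, qy;
      double d = nearest_wall_dist(x[i], y[i], qx, qy);
      if (d > 0 && d < rc) e += wca_energy(d, p.sigma, p.eps);
    }
    return e;
  }

  double wall_sweep(const std::vector<int> &movable) {
    int nw = (int)wx.size();
    if (nw < 3) stop("wall polygon needs at least 3 nodes");
    std::vector<int> order = movable;
    if (order.empty()) { order.resize(nw); for (int k = 0; k < nw; ++k) order[k] = k; }
    for (int h = (int)order.size() - 1; h > 0; --h)
      std::swap(order[h], order[rng_wall.unif_int(h + 1)]);

    double rc = wca_cut(p.sigma);
    int n_acc = 0;
    for (size_t h = 0; h < order.size(); ++h) {
      int k = order[h];
      double dx = rng_wall.unif_ab(-p.delta_wall, p.delta_wall);
      double dy = rng_wall.unif_ab(-p.delta_wall, p.delta_wall);

      // monomers whose wall energy can change: near the two moved segments
      std::vector<int> cand;
      double reach = p.wall_l0 + rc + p.delta_wall + 0.5;
      for (size_t q = 0; q < wall_near.size(); ++q) {
        int i = wall_near[q];
        double ex = x[i] - wx[k], ey = y[i] - wy[k];
        if (std::sqrt(ex * ex + ey * ey) < reach) cand.push_back(i);
      }

      double e0 = wall_local_energy(k) + wall_monomer_energy(cand);
      double a0 = signed_area();
      wx[k] += dx; wy[k] += dy;
      double e1 = wall_local_energy(k) + wall_monomer_energy(cand);
      double a1 = signed_area();
      double dE = e1 - e0 + p.P * p.Z * orient * (a1 - a0);
      if (dE <= 0 || rng_wall.unif() < std::exp(-dE / p.kT)) {
        ++n_acc;
      } else {
        wx[k] -= dx; wy[k] -= dy;
      }
    }
    return (double)n_acc / order.size();
  }

  // --- scheduler -----------------------------------------------------------
  List advance(long nsteps, bool do_kinetics, bool do_wall) {
    long att = 0, mov = 0, det = 0, edet = 0;
    double acc_sum = 0; long acc_n = 0;
    std::vector<int> all;
    for (long s = 0; s < nsteps; ++s) {
      bd_step();
      if (do_kinetics && (step_count % p.kinetics_interval == 0)) {
        List rep = kinetics_sweep();
        att += as<int>(rep["n_attached"]); mov += as<int>(rep["n_moved"]);
        det += as<int>(rep["n_detached"]); edet += as<int>(rep["n_end_detached"]);
      }
      if (do_wall && !p.fixed_volume && (step_count % p.wall_interval == 0)) {
        if (list_age > 0 && wall_near.empty()) build_lists();
        acc_sum += wall_sweep(all);
        ++acc_n;
      }
      if (s % 4096 == 0) Rcpp::checkUserInterrupt();
    }
    int n_plus = 0;
    for (size_t q = 0; q < motors.size(); ++q)
      if (motors[q][1] >= p.M - 1 || motors[q][3] >= p.M - 1) ++n_plus;
    return List::create(
      _["n_attached"] = (double)att, _["n_moved"] = (double)mov,
      _["n_detached"] = (double)det, _["n_end_detached"] = (double)edet,
      _["n_mot"] = (int)motors.size(), _["n_mot_plus"] = n_plus,
      _["wall_acceptance"] = acc_n > 0 ? acc_sum / acc_n : NA_REAL);
  }
};

// ---------------------------------------------------------------------------
// Construction helpers shared by the exported entry points
// ---------------------------------------------------------------------------

static GelSim *make_sim(const List &par, const NumericMatrix &pos,
                        const IntegerMatrix &motors, const NumericMatrix &wall,
                        double seed) {
  GelSim *s = new GelSim();
  s->p = parse_params(par);
  s->nm = s->p.N * s->p.M;
  if (pos.nrow() != s->nm || pos.ncol() != 3)
    stop("positions must be an (N*M) x 3 matrix");
  s->x.resize(s->nm); s->y.resize(s->nm); s->z.resize(s->nm);
  s->fx.assign(s->nm, 0); s->fy.assign(s->nm, 0); s->fz.assign(s->nm, 0);
  for (int i = 0; i < s->nm; ++i) {
    s->x[i] = pos(i, 0); s->y[i] = pos(i, 1); s->z[i] = pos(i, 2);
  }
  for (int q = 0; q < motors.nrow(); ++q) {
    std::array<int, 4> mo = {motors(q, 0), motors(q, 1), motors(q, 2), motors(q, 3)};
    if (mo[0] == mo[2]) stop("motor %d connects a filament to itself", q + 1);
    for (int c = 0; c < 2; ++c) {
      if (mo[2 * c] < 0 || mo[2 * c] >= s->p.N || mo[2 * c + 1] < 0 ||
          mo[2 * c + 1] >= s->p.M)
        stop("motor %d references a non-existent monomer", q + 1);
    }
    s->motors.push_back(mo);
  }
  int nw = wall.nrow();
  s->wx.resize(nw); s->wy.resize(nw);
  for (int k = 0; k < nw; ++k) { s->wx[k] = wall(k, 0); s->wy[k] = wall(k, 1); }
  if (nw >= 3) s->orient = s->signed_area() >= 0 ? 1.0 : -1.0;
  uint64_t sd = (uint64_t)seed;
  uint64_t base = sd;
  s->rng_bd.seed(splitmix64(base));
  s->rng_kin.seed(splitmix64(base));
  s->rng_wall.seed(splitmix64(base));
  return s;
}

// [[Rcpp::export]]
SEXP sim_create_cpp(List par, NumericMatrix pos, IntegerMatrix motors,
                    NumericMatrix wall, double seed) {
  GelSim *s = make_sim(par, pos, motors, wall, seed);
  XPtr<GelSim> ptr(s, true);
  return ptr;
}

// [[Rcpp::export]]
List sim_advance_cpp(SEXP xp, double nsteps, bool do_kinetics, bool do_wall) {
  XPtr<GelSim> s(xp);
  return s->advance((long)nsteps, do_kinetics, do_wall);
}

// [[Rcpp::export]]
List sim_kinetics_cpp(SEXP xp, bool do_attach, bool do_move, bool do_detach) {
  XPtr<GelSim> s(xp);
  return s->kinetics_sweep(do_attach, do_move, do_detach);
}

// [[Rcpp::export]]
double sim_wall_sweep_cpp(SEXP xp, IntegerVector movable) {
  XPtr<GelSim> s(xp);
  if (s->list_age > (1 << 20)) s->build_lists();
  std::vector<int> mv(movable.begin(), movable.end());
  return s->wall_sweep(mv);
}

// [[Rcpp::export]]
List sim_state_cpp(SEXP xp) {
  XPtr<GelSim> s(xp);
  NumericMatrix pos(s->nm, 3);
  for (int i = 0; i < s->nm; ++i) {
    pos(i, 0) = s->x[i]; pos(i, 1) = s->y[i]; pos(i, 2) = s->z[i];
  }
  IntegerMatrix mo((int)s->motors.size(), 4);
  for (int q = 0; q < (int)s->motors.size(); ++q)
    for (int c = 0; c < 4; ++c) mo(q, c) = s->motors[q][c];
  NumericMatrix wl((int)s->wx.size(), 2);
  for (int k = 0; k < (int)s->wx.size(); ++k) {
    wl(k, 0) = s->wx[k]; wl(k, 1) = s->wy[k];
  }
  return List::create(_["positions"] = pos, _["motors"] = mo, _["wall"] = wl,
                      _["time"] = s->time, _["steps"] = (double)s->step_count);
}

// [[Rcpp::export]]
List sim_energy_cpp(SEXP xp) {
  XPtr<GelSim> s(xp);
  EnergyTerms e = s->compute_forces(false);
  double stretch = 0, bend = 0, pv = 0;
  if (s->wx.size() >= 3 && !s->p.fixed_volume) {
    int nw = (int)s->wx.size();
    for (int k = 0; k < nw; ++k) {
      int k2 = (k + 1) % nw;
      double dx = s->wx[k2] - s->wx[k], dy = s->wy[k2] - s->wy[k];
      double dl = std::sqrt(dx * dx + dy * dy) - s->p.wall_l0;
      stretch += s->p.c_stretch * s->p.kT * s->p.Z * dl * dl / std::pow(s->p.wall_l0, 3);
      double dk = s->turn_angle(k) / s->p.wall_l0 - s->p.wall_kappa0;
      bend += s->p.c_bend * s->p.kT * s->p.wall_l0 * s->p.Z * dk * dk;
    }
    pv = s->p.P * s->p.Z * s->orient * s->signed_area();
  }
  return List::create(
    _["bond"] = e.bond, _["bend"] = e.bend, _["excluded_volume"] = e.ev,
    _["z_walls"] = e.zwall, _["side_wall"] = e.sidewall,
    _["motor_springs"] = e.motor, _["wall_stretch"] = stretch,
    _["wall_bend"] = bend, _["pressure_volume"] = pv);
}

// [[Rcpp::export]]
void sim_set_radius_cpp(SEXP xp, double R) {
  XPtr<GelSim> s(xp);
  s->p.fixed_radius = R;
  s->list_age = 1 << 30; // radius change invalidates wall-near list
}

// Stateless reference evaluation of energies and forces (brute-force pairs).
// [[Rcpp::export]]
List energy_forces_cpp(List par, NumericMatrix pos, IntegerMatrix motors,
                       NumericMatrix wall, bool use_nlist) {
  GelSim *s = make_sim(par, pos, motors, wall, 1.0);
  EnergyTerms e = s->compute_forces(use_nlist);
  NumericMatrix f(s->nm, 3);
  for (int i = 0; i < s->nm; ++i) {
    f(i, 0) = s->fx[i]; f(i, 1) = s->fy[i]; f(i, 2) = s->fz[i];
  }
  List out = List::create(
    _["bond"] = e.bond, _["bend"] = e.bend, _["excluded_volume"] = e.ev,
    _["z_walls"] = e.zwall, _["side_wall"] = e.sidewall,
    _["motor_springs"] = e.motor, _["forces"] = f);
  delete s;
  return out;
}

// [[Rcpp::export]]
List wall_energy_cpp(NumericMatrix wall, double l0, double kappa0,
                     double c_stretch, double c_bend, double Z, double kT) {
  int nw = wall.nrow();
  if (nw < 3) stop("wall polygon needs at least 3 nodes");
  std::vector<double> wx(nw), wy(nw);
  for (int k = 0; k < nw; ++k) { wx[k] = wall(k, 0); wy[k] = wall(k, 1); }
  double stretch = 0, bend = 0;
  for (int k = 0; k < nw; ++k) {
    int k2 = (k + 1) % nw;
    double dx = wx[k2] - wx[k], dy = wy[k2] - wy[k];
    double dl = std::sqrt(dx * dx + dy * dy) - l0;
    stretch += c_stretch * kT * Z * dl * dl / (l0 * l0 * l0);
    int km = (k + nw - 1) % nw, kp = (k + 1) % nw;
    double ux = wx[k] - wx[km], uy = wy[k] - wy[km];
    double vx = wx[kp] - wx[k], vy = wy[kp] - wy[k];
    double phi = std::atan2(ux * vy - uy * vx, ux * vx + uy * vy);
    double dk = phi / l0 - kappa0;
    bend += c_bend * kT * l0 * Z * dk * dk;
  }
  return List::create(_["stretch"] = stretch, _["bend"] = bend);
}

// [[Rcpp::export]]
double polygon_area_cpp(NumericMatrix wall) {
  int nw = wall.nrow();
  double a = 0;
  for (int k = 0; k < nw; ++k) {
    int k2 = (k + 1) % nw;
    a += wall(k, 0) * wall(k2, 1) - wall(k2, 0) * wall(k, 1);
  }
  return 0.5 * a;
}
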