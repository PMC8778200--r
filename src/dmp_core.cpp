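// Coupled SPH / lattice-spring solver core.
//
// Particle kinds: 0 = fluid, 1 = membrane (mobile), 2 = membrane (fixed row),
// 3 = tank wall.  Kinds 2 and 3 never move; kind 1 integrates under spring,
// tether, damping, motility and fluid-reaction forces; kind 0 under SPH
// pressure, Monaghan viscosity, gravity and wall contact/no-slip forces.
//
// Two-length scheme: the continuity equation uses smoothing length h, the
// momentum equation (pressure + viscosity) uses h_M.  Density evolves by the
// discretised continuity equation (free-surface safe).  Pressure from the
// Tait equation of state.  All pair forces are accumulated antisymmetrically
// so linear momentum is conserved to round-off.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static const int KIND_FLUID = 0;
static const int KIND_MOBILE = 1;

// ---------------------------------------------------------------------------
// Lucy kernel, 3-D: W(r,h) = 105/(16 pi h^3) (1 + 3q)(1 - q)^3, q = r/h < 1
static inline double lucy_w(double r, double h) {
  if (r >= h) return 0.0;
  double q = r / h, om = 1.0 - q;
  return 105.0 / (16.0 * M_PI * h * h * h) * (1.0 + 3.0 * q) * om * om * om;
}
// dW/dr = -315/(4 pi h^4) q (1 - q)^2
static inline double lucy_dw(double r, double h) {
  if (r >= h) return 0.0;
  double q = r / h, om = 1.0 - q;
  return -315.0 / (4.0 * M_PI * h * h * h * h) * q * om * om;
}

// [[Rcpp::export]]
List cpp_lucy(NumericVector r, double h) {
  int n = r.size();
  NumericVector W(n), dW(n);
  for (int i = 0; i < n; ++i) { W[i] = lucy_w(r[i], h); dW[i] = lucy_dw(r[i], h); }
  return List::create(_["w"] = W, _["dw"] = dW);
}

// Tait equation of state: P = c0^2 rho0 / 7 [ (rho/rho0)^7 - 1 ]
static inline double tait_p(double rho, double rho0, double c0) {
  double x = rho / rho0;
  double x7 = x * x; x7 *= x7; x7 *= x7; x7 /= x;   // x^7
  return c0 * c0 * rho0 / 7.0 * (x7 - 1.0);
}

// [[Rcpp::export]]
NumericVector cpp_tait(NumericVector rho, double rho0, double c0) {
  int n = rho.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = tait_p(rho[i], rho0, c0);
  return out;
}

// ---------------------------------------------------------------------------
// Simulation scratch state

struct Periodic {
  bool px, py, pz;
  double x0, x1, y0, y1, z0, z1;
  Periodic() : px(false), py(false), pz(false),
               x0(0), x1(0), y0(0), y1(0), z0(0), z1(0) {}
  inline void minimg(double &dx, double &dy, double &dz) const {
    if (px) { double L = x1 - x0; dx -= L * std::round(dx / L); }
    if (py) { double L = y1 - y0; dy -= L * std::round(dy / L); }
    if (pz) { double L = z1 - z0; dz -= L * std::round(dz / L); }
  }
  inline void wrap(double &x, double &y, double &z) const {
    if (px) { double L = x1 - x0; x -= L * std::floor((x - x0) / L); }
    if (py) { double L = y1 - y0; y -= L * std::floor((y - y0) / L); }
    if (pz) { double L = z1 - z0; z -= L * std::floor((z - z0) / L); }
  }
};

struct SimState {
  int n;
  std::vector<double> x, y, z, vx, vy, vz, m, rho, P;
  std::vector<int> kind, seg;
};

struct SphPar {
  double h, hM, c0, b, alpha, rho0, gx, gy, gz, A, rc, wall_visc;
};

struct Motility {
  bool on;
  double amp_con, amp_rel, T, f_relax, f_con, f_ret;
  int only_seg;            // -1 = all segments active
  Motility() : on(false), amp_con(0), amp_rel(0), T(1),
               f_relax(0.3), f_con(0.3), f_ret(1.4), only_seg(-1) {}
  // signed radial force magnitude (positive = inward) for segment s at time t
  inline double force(int s, double t) const {
    if (!on || s < 1) return 0.0;
    if (only_seg > 0 && s != only_seg) return 0.0;
    double ph = t - (s - 1) * T;
    if (ph < 0) return 0.0;
    if (ph < f_relax * T) return -amp_rel;
    if (ph < (f_relax + f_con) * T) return amp_con;
    double t2 = (f_relax + f_con) * T;
    if (ph < t2 + f_ret * T) return amp_con * (1.0 - (ph - t2) / (f_ret * T));
    return 0.0;
  }
};

struct Springs {
  std::vector<int> bi, bj;
  std::vector<double> l0;
  double kb, kp, kv;
  std::vector<double> ax, ay, az;  // tether anchors (all particles; used for kind 1)
};

// ---------------------------------------------------------------------------
// Pair enumeration: linked-cell list with half-shell traversal, falling back
// to a brute-force O(n^2) sweep for small systems or under-resolved periodic
// boxes (where cell images would alias).

template <typename F>
static void for_each_pair(const SimState &S, double cut, const Periodic &per, F &&fun) {
  const double cut2 = cut * cut;
  int n = S.n;

  double lox, hix, loy, hiy, loz, hiz;
  if (per.px) { lox = per.x0; hix = per.x1; } else {
    lox = hix = S.x[0];
    for (int i = 1; i < n; ++i) { lox = std::min(lox, S.x[i]); hix = std::max(hix, S.x[i]); }
    lox -= 1e-9; hix += 1e-9;
  }
  if (per.py) { loy = per.y0; hiy = per.y1; } else {
    loy = hiy = S.y[0];
    for (int i = 1; i < n; ++i) { loy = std::min(loy, S.y[i]); hiy = std::max(hiy, S.y[i]); }
    loy -= 1e-9; hiy += 1e-9;
  }
  if (per.pz) { loz = per.z0; hiz = per.z1; } else {
    loz = hiz = S.z[0];
    for (int i = 1; i < n; ++i) { loz = std::min(loz, S.z[i]); hiz = std::max(hiz, S.z[i]); }
    loz -= 1e-9; hiz += 1e-9;
  }

  int ncx = std::max(1, (int)std::floor((hix - lox) / cut));
  int ncy = std::max(1, (int)std::floor((hiy - loy) / cut));
  int ncz = std::max(1, (int)std::floor((hiz - loz) / cut));

  bool brute = (n < 300) ||
    (per.px && ncx < 3) || (per.py && ncy < 3) || (per.pz && ncz < 3) ||
    ((double)ncx * ncy * ncz > 4e7);  // runaway particle inflated the box

  if (brute) {
    for (int i = 0; i < n - 1; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double dx = S.x[i] - S.x[j], dy = S.y[i] - S.y[j], dz = S.z[i] - S.z[j];
        per.minimg(dx, dy, dz);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 < cut2) fun(i, j, dx, dy, dz, r2);
      }
    }
    return;
  }

  double sx = (hix - lox) / ncx, sy = (hiy - loy) / ncy, sz = (hiz - loz) / ncz;
  std::vector<int> head((size_t)ncx * ncy * ncz, -1), nxt(n);
  std::vector<int> cix(n), ciy(n), ciz(n);
  for (int i = 0; i < n; ++i) {
    int ix = std::min(ncx - 1, std::max(0, (int)((S.x[i] - lox) / sx)));
    int iy = std::min(ncy - 1, std::max(0, (int)((S.y[i] - loy) / sy)));
    int iz = std::min(ncz - 1, std::max(0, (int)((S.z[i] - loz) / sz)));
    cix[i] = ix; ciy[i] = iy; ciz[i] = iz;
    size_t c = (size_t)ix + (size_t)ncx * (iy + (size_t)ncy * iz);
    nxt[i] = head[c]; head[c] = i;
  }

  // half shell: 13 neighbour offsets + same cell (j after i)
  static const int off[13][3] = {
    {1,0,0}, {-1,1,0}, {0,1,0}, {1,1,0},
    {-1,-1,1}, {0,-1,1}, {1,-1,1}, {-1,0,1}, {0,0,1}, {1,0,1},
    {-1,1,1}, {0,1,1}, {1,1,1}
  };

  for (int iz = 0; iz < ncz; ++iz)
  for (int iy = 0; iy < ncy; ++iy)
  for (int ix = 0; ix < ncx; ++ix) {
    size_t c = (size_t)ix + (size_t)ncx * (iy + (size_t)ncy * iz);
    for (int i = head[c]; i >= 0; i = nxt[i]) {
      // same cell
      for (int j = nxt[i]; j >= 0; j = nxt[j]) {
        double dx = S.x[i] - S.x[j], dy = S.y[i] - S.y[j], dz = S.z[i] - S.z[j];
        per.minimg(dx, dy, dz);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 < cut2) fun(i, j, dx, dy, dz, r2);
      }
      // neighbour cells
      for (int k = 0; k < 13; ++k) {
        int jx = ix + off[k][0], jy = iy + off[k][1], jz = iz + off[k][2];
        if (per.px) jx = (jx + ncx) % ncx; else if (jx < 0 || jx >= ncx) continue;
        if (per.py) jy = (jy + ncy) % ncy; else if (jy < 0 || jy >= ncy) continue;
        if (per.pz) jz = (jz + ncz) % ncz; else if (jz < 0 || jz >= ncz) continue;
        size_t c2 = (size_t)jx + (size_t)ncx * (jy + (size_t)ncy * jz);
        for (int j = head[c2]; j >= 0; j = nxt[j]) {
          double dx = S.x[i] - S.x[j], dy = S.y[i] - S.y[j], dz = S.z[i] - S.z[j];
          per.minimg(dx, dy, dz);
          double r2 = dx * dx + dy * dy + dz * dz;
          if (r2 < cut2) fun(i, j, dx, dy, dz, r2);
        }
      }
    }
  }
}

// ---------------------------------------------------------------------------
// Verlet pair list: stores pairs within cut + skin that involve at least one
// fluid particle (membrane-membrane interactions run through the bond list),
// rebuilt whenever any mobile particle has moved more than skin / 2.

struct PairList {
  std::vector<int> pi, pj;
  void clear() { pi.clear(); pj.clear(); }
};

static void build_pairs(const SimState &S, double cut_list, const Periodic &per,
                        PairList &pl) {
  pl.clear();
  for_each_pair(S, cut_list, per,
                [&](int i, int j, double, double, double, double) {
    if (S.kind[i] != KIND_FLUID && S.kind[j] != KIND_FLUID) return;
    pl.pi.push_back(i);
    pl.pj.push_back(j);
  });
}

// ---------------------------------------------------------------------------
// Force evaluation.  Fills F (N) and drho (kg m^-3 s^-1); returns the minimum
// fluid-wall pair distance seen (for penetration diagnostics).

struct Forces {
  std::vector<double> fx, fy, fz, drho;
  double min_fw;
};

static void compute_forces(const SimState &S, const SphPar &p, const Springs &sp,
                           const Motility &mot, const Periodic &per, double t,
                           const PairList &pl, Forces &out,
                           double gravity_scale = 1.0) {
  int n = S.n;
  out.fx.assign(n, 0.0); out.fy.assign(n, 0.0); out.fz.assign(n, 0.0);
  out.drho.assign(n, 0.0);
  out.min_fw = R_PosInf;

  const double h = p.h, hM = p.hM, rc = p.rc;
  const double hM2 = hM * hM;
  const double cut = std::max(hM, rc);
  const double cut2 = cut * cut;
  const double eps2 = 1e-24;

  // Fluid pressure from the Tait EOS, clamped at zero: the partially filled
  // lumen has a free surface, and letting the stretched surface carry
  // tension drives the classic tensile clumping instability.  A free
  // surface against gas cannot sustain tension, so P >= 0.
  SimState &Sm = const_cast<SimState &>(S);  // pressures cached in S.P
  for (int i = 0; i < n; ++i)
    Sm.P[i] = (S.kind[i] == KIND_FLUID)
      ? std::max(tait_p(S.rho[i], p.rho0, p.c0), 0.0) : 0.0;

  double min_fw = R_PosInf;

  const size_t np = pl.pi.size();
  for (size_t k = 0; k < np; ++k) {
    const int i = pl.pi[k], j = pl.pj[k];
    double dx = S.x[i] - S.x[j], dy = S.y[i] - S.y[j], dz = S.z[i] - S.z[j];
    per.minimg(dx, dy, dz);
    const double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= cut2) continue;
    int ki = S.kind[i], kj = S.kind[j];
    bool fi = (ki == KIND_FLUID), fj = (kj == KIND_FLUID);
    if (r2 < eps2) continue;  // coincident pair: no direction, skip
    double r = std::sqrt(r2);
    double dvx = S.vx[i] - S.vx[j], dvy = S.vy[i] - S.vy[j], dvz = S.vz[i] - S.vz[j];
    double vr = dvx * dx + dvy * dy + dvz * dz;

    double fs = 0.0;
    if (fi && fj) {
      // continuity (smoothing length h), fluid pairs only
      if (r < h) {
        double dw = lucy_dw(r, h) / r;       // gradW_i = dw * (ri - rj)
        double s = vr * dw;
        out.drho[i] += S.m[j] * s;
        out.drho[j] += S.m[i] * s;
        // symmetric pressure term: evaluated with the density smoothing
        // length h, whose kernel keeps the nearest shell on the stable
        // branch (the h_M = 4 spacings kernel is Swegle-unstable under
        // compression)
        double coefp = S.P[i] / (S.rho[i] * S.rho[i]) +
                       S.P[j] / (S.rho[j] * S.rho[j]);
        fs -= S.m[i] * S.m[j] * coefp * dw;
      }
      // unconditional Monaghan viscosity at the momentum smoothing length
      // h_M throughout, matching its effective viscosity nu = alpha h_M c0/10
      if (r < hM) {
        double rbar = 0.5 * (S.rho[i] + S.rho[j]);
        double piv = -p.alpha * hM * p.c0 * vr / (rbar * (r2 + p.b * hM2));
        fs -= S.m[i] * S.m[j] * piv * lucy_dw(r, hM) / r;
      }
    } else {
      // fluid-wall pair: no-slip viscous coupling (the wall side enters as a
      // ghost fluid particle at the fluid's mass; the symmetric-mirror
      // factor wall_visc doubles the relative velocity) + contact repulsion
      if (r < min_fw) min_fw = r;
      if (r < hM) {
        double mf = fi ? S.m[i] : S.m[j];
        double rbar = 0.5 * (S.rho[i] + S.rho[j]);
        double piv = -p.wall_visc * p.alpha * hM * p.c0 * vr /
                     (rbar * (r2 + p.b * hM2));
        fs -= mf * mf * piv * lucy_dw(r, hM) / r;
      }
      if (r < rc) {
        double fc = p.A * M_PI / rc * std::sin(M_PI * r / rc) / r;
        out.fx[i] += fc * dx; out.fy[i] += fc * dy; out.fz[i] += fc * dz;
        out.fx[j] -= fc * dx; out.fy[j] -= fc * dy; out.fz[j] -= fc * dz;
      }
    }
    if (fs != 0.0) {
      out.fx[i] += fs * dx; out.fy[i] += fs * dy; out.fz[i] += fs * dz;
      out.fx[j] -= fs * dx; out.fy[j] -= fs * dy; out.fz[j] -= fs * dz;
    }
  }
  out.min_fw = min_fw;

  // body force (gravity) on fluid; ramped up during quasi-static settling
  for (int i = 0; i < n; ++i) {
    if (S.kind[i] == KIND_FLUID) {
      out.fx[i] += S.m[i] * p.gx * gravity_scale;
      out.fy[i] += S.m[i] * p.gy * gravity_scale;
      out.fz[i] += S.m[i] * p.gz * gravity_scale;
    }
  }

  // lattice springs (bonds), Hooke F_ij = k (r_ij - r0) along the bond
  int nb = sp.bi.size();
  for (int b = 0; b < nb; ++b) {
    int i = sp.bi[b], j = sp.bj[b];
    double dx = S.x[j] - S.x[i], dy = S.y[j] - S.y[i], dz = S.z[j] - S.z[i];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-12) continue;
    double f = sp.kb * (r - sp.l0[b]) / r;
    out.fx[i] += f * dx; out.fy[i] += f * dy; out.fz[i] += f * dz;
    out.fx[j] -= f * dx; out.fy[j] -= f * dy; out.fz[j] -= f * dz;
  }

  // tethers, damping, motility on mobile membrane particles
  for (int i = 0; i < n; ++i) {
    if (S.kind[i] != KIND_MOBILE) continue;
    out.fx[i] += sp.kp * (sp.ax[i] - S.x[i]);
    out.fy[i] += sp.kp * (sp.ay[i] - S.y[i]);
    out.fz[i] += sp.kp * (sp.az[i] - S.z[i]);
    out.fx[i] -= sp.kv * S.vx[i];
    out.fy[i] -= sp.kv * S.vy[i];
    out.fz[i] -= sp.kv * S.vz[i];
    if (mot.on && S.seg[i] >= 1) {
      double fin = mot.force(S.seg[i], t);
      if (fin != 0.0) {
        double rr = std::sqrt(S.y[i] * S.y[i] + S.z[i] * S.z[i]);
        if (rr > 1e-12) {
          out.fy[i] -= fin * S.y[i] / rr;
          out.fz[i] -= fin * S.z[i] / rr;
        }
      }
    }
  }
}

// ---------------------------------------------------------------------------
// Helpers to unpack R inputs

static SimState unpack_state(NumericMatrix pos, NumericMatrix vel, NumericVector mass,
                             NumericVector dens, IntegerVector kind, IntegerVector seg) {
  SimState S;
  S.n = pos.nrow();
  S.x.resize(S.n); S.y.resize(S.n); S.z.resize(S.n);
  S.vx.resize(S.n); S.vy.resize(S.n); S.vz.resize(S.n);
  S.m.resize(S.n); S.rho.resize(S.n); S.P.resize(S.n);
  S.kind.resize(S.n); S.seg.resize(S.n);
  for (int i = 0; i < S.n; ++i) {
    S.x[i] = pos(i, 0); S.y[i] = pos(i, 1); S.z[i] = pos(i, 2);
    S.vx[i] = vel(i, 0); S.vy[i] = vel(i, 1); S.vz[i] = vel(i, 2);
    S.m[i] = mass[i]; S.rho[i] = dens[i];
    S.kind[i] = kind[i]; S.seg[i] = seg[i];
  }
  return S;
}

static SphPar unpack_sph(List par) {
  SphPar p;
  p.h = par["h"]; p.hM = par["h_m"]; p.c0 = par["c0"]; p.b = par["b"];
  p.alpha = par["alpha"]; p.rho0 = par["rho0"];
  NumericVector g = par["gravity"];
  p.gx = g[0]; p.gy = g[1]; p.gz = g[2];
  p.A = par["contact_a"]; p.rc = par["contact_rc"];
  p.wall_visc = par["wall_visc_scale"];
  return p;
}

static Springs unpack_springs(List spr, int n) {
  Springs sp;
  sp.kb = spr["k_bond"]; sp.kp = spr["k_tether"]; sp.kv = spr["k_damp"];
  IntegerVector bi = spr["bond_i"], bj = spr["bond_j"];
  NumericVector l0 = spr["bond_l0"];
  sp.bi.assign(bi.begin(), bi.end());
  sp.bj.assign(bj.begin(), bj.end());
  for (size_t k = 0; k < sp.bi.size(); ++k) { sp.bi[k]--; sp.bj[k]--; }  // 1- to 0-based
  sp.l0.assign(l0.begin(), l0.end());
  NumericMatrix anc = spr["anchors"];
  sp.ax.resize(n); sp.ay.resize(n); sp.az.resize(n);
  for (int i = 0; i < n; ++i) { sp.ax[i] = anc(i, 0); sp.ay[i] = anc(i, 1); sp.az[i] = anc(i, 2); }
  return sp;
}

static Motility unpack_motility(List mo) {
  Motility m;
  m.on = as<bool>(mo["on"]);
  if (m.on) {
    m.amp_con = mo["amp_contract"]; m.amp_rel = mo["amp_relax"];
    m.T = mo["segment_period"];
    m.f_relax = mo["f_relax"]; m.f_con = mo["f_contract"]; m.f_ret = mo["f_return"];
    m.only_seg = mo["only_segment"];
  }
  return m;
}

static Periodic unpack_periodic(List pe) {
  Periodic per;
  per.px = as<bool>(pe["px"]); per.py = as<bool>(pe["py"]); per.pz = as<bool>(pe["pz"]);
  NumericVector lo = pe["lo"], hi = pe["hi"];
  per.x0 = lo[0]; per.y0 = lo[1]; per.z0 = lo[2];
  per.x1 = hi[0]; per.y1 = hi[1]; per.z1 = hi[2];
  return per;
}

// ---------------------------------------------------------------------------
// Single force/rate evaluation (used by the R-level operators and tests)

// [[Rcpp::export]]
List cpp_forces(NumericMatrix pos, NumericMatrix vel, NumericVector mass,
                NumericVector dens, IntegerVector kind, IntegerVector seg,
                List sph, List springs, List motility, List periodic, double t) {
  SimState S = unpack_state(pos, vel, mass, dens, kind, seg);
  SphPar p = unpack_sph(sph);
  Springs sp = unpack_springs(springs, S.n);
  Motility mo = unpack_motility(motility);
  Periodic per = unpack_periodic(periodic);
  PairList pl;
  build_pairs(S, std::max(p.hM, p.rc), per, pl);
  Forces F;
  compute_forces(S, p, sp, mo, per, t, pl, F);
  NumericMatrix fm(S.n, 3);
  NumericVector dr(S.n);
  for (int i = 0; i < S.n; ++i) {
    fm(i, 0) = F.fx[i]; fm(i, 1) = F.fy[i]; fm(i, 2) = F.fz[i];
    dr[i] = F.drho[i];
  }
  return List::create(_["force"] = fm, _["drho"] = dr, _["min_fluid_wall"] = F.min_fw);
}

// ---------------------------------------------------------------------------
// Main time loop: velocity Verlet with explicit continuity-density update.

// [[Rcpp::export]]
List cpp_run(NumericMatrix pos, NumericMatrix vel, NumericVector mass,
             NumericVector dens, IntegerVector kind, IntegerVector seg,
             List sph, List springs, List motility, List periodic,
             double t0, double dt, int nsteps,
             int snapshot_every, double settle_until, double settle_damp,
             double vmax_abort) {
  SimState S = unpack_state(pos, vel, mass, dens, kind, seg);
  SphPar p = unpack_sph(sph);
  Springs sp = unpack_springs(springs, S.n);
  Motility mo = unpack_motility(motility);
  Periodic per = unpack_periodic(periodic);

  int n = S.n;
  Forces F;
  double t = t0;

  // Verlet list with skin; rebuilt when any mobile particle has moved > skin/2
  const double skin = 0.5 * p.h;
  const double cut_list = std::max(p.hM, p.rc) + skin;
  const double half_skin2 = 0.25 * skin * skin;
  PairList pl;
  build_pairs(S, cut_list, per, pl);
  std::vector<double> dpx(n, 0.0), dpy(n, 0.0), dpz(n, 0.0);

  // gravity ramps up over the first 70% of the settling phase so the fresh
  // lattice loads the walls quasi-statically
  auto gscale = [&](double tt) {
    if (tt >= settle_until || settle_until <= t0) return 1.0;
    double den = 0.7 * (settle_until - t0);
    return den > 0 ? std::min(1.0, (tt - t0) / den) : 1.0;
  };

  compute_forces(S, p, sp, mo, per, t, pl, F, gscale(t));

  std::vector<NumericMatrix> snap_pos, snap_vel;
  std::vector<NumericVector> snap_rho;
  std::vector<double> snap_t;
  std::vector<double> diag_t, diag_ke, diag_vmax, diag_rhomin, diag_rhomax, diag_minfw;
  double run_minfw = F.min_fw;

  auto record = [&](double tt, bool want_snapshot) {
    double ke = 0, vmax = 0, rmin = R_PosInf, rmax = 0;
    for (int i = 0; i < n; ++i) {
      double v2 = S.vx[i] * S.vx[i] + S.vy[i] * S.vy[i] + S.vz[i] * S.vz[i];
      ke += 0.5 * S.m[i] * v2;
      vmax = std::max(vmax, std::sqrt(v2));
      if (S.kind[i] == KIND_FLUID) { rmin = std::min(rmin, S.rho[i]); rmax = std::max(rmax, S.rho[i]); }
    }
    diag_t.push_back(tt); diag_ke.push_back(ke); diag_vmax.push_back(vmax);
    diag_rhomin.push_back(rmin); diag_rhomax.push_back(rmax);
    diag_minfw.push_back(run_minfw);
    run_minfw = R_PosInf;
    if (!want_snapshot) return;
    NumericMatrix sp_(n, 3), sv(n, 3);
    NumericVector sr(n);
    for (int i = 0; i < n; ++i) {
      sp_(i, 0) = S.x[i]; sp_(i, 1) = S.y[i]; sp_(i, 2) = S.z[i];
      sv(i, 0) = S.vx[i]; sv(i, 1) = S.vy[i]; sv(i, 2) = S.vz[i];
      sr[i] = S.rho[i];
    }
    snap_pos.push_back(sp_); snap_vel.push_back(sv); snap_rho.push_back(sr);
    snap_t.push_back(tt);
  };

  std::string status = "ok";
  if (snapshot_every > 0) record(t, t >= settle_until);

  for (int step = 1; step <= nsteps; ++step) {
    bool settling = (t < settle_until);

    // half kick (velocity and density, rates from the last force evaluation)
    for (int i = 0; i < n; ++i) {
      S.rho[i] += 0.5 * dt * F.drho[i];  // walls included: frozen SPH particles
      if (S.kind[i] > KIND_MOBILE) continue;
      double im = 0.5 * dt / S.m[i];
      S.vx[i] += F.fx[i] * im; S.vy[i] += F.fy[i] * im; S.vz[i] += F.fz[i] * im;
    }
    if (settling && settle_damp < 1.0) {
      for (int i = 0; i < n; ++i) {
        if (S.kind[i] > KIND_MOBILE) continue;
        S.vx[i] *= settle_damp; S.vy[i] *= settle_damp; S.vz[i] *= settle_damp;
      }
    }
    // drift
    bool rebuild = false;
    for (int i = 0; i < n; ++i) {
      if (S.kind[i] > KIND_MOBILE) continue;
      S.x[i] += dt * S.vx[i]; S.y[i] += dt * S.vy[i]; S.z[i] += dt * S.vz[i];
      per.wrap(S.x[i], S.y[i], S.z[i]);
      dpx[i] += dt * S.vx[i]; dpy[i] += dt * S.vy[i]; dpz[i] += dt * S.vz[i];
      if (dpx[i] * dpx[i] + dpy[i] * dpy[i] + dpz[i] * dpz[i] > half_skin2)
        rebuild = true;
    }
    if (rebuild) {
      build_pairs(S, cut_list, per, pl);
      std::fill(dpx.begin(), dpx.end(), 0.0);
      std::fill(dpy.begin(), dpy.end(), 0.0);
      std::fill(dpz.begin(), dpz.end(), 0.0);
    }
    t += dt;
    compute_forces(S, p, sp, mo, per, t, pl, F, gscale(t));
    run_minfw = std::min(run_minfw, F.min_fw);
    // half kick with the new rates
    for (int i = 0; i < n; ++i) {
      S.rho[i] += 0.5 * dt * F.drho[i];
      if (S.kind[i] > KIND_MOBILE) continue;
      double im = 0.5 * dt / S.m[i];
      S.vx[i] += F.fx[i] * im; S.vy[i] += F.fy[i] * im; S.vz[i] += F.fz[i] * im;
    }

    // stability checks (after the settling phase)
    if (!settling) {
      bool bad = false;
      for (int i = 0; i < n && !bad; ++i) {
        double v2 = S.vx[i] * S.vx[i] + S.vy[i] * S.vy[i] + S.vz[i] * S.vz[i];
        if (!std::isfinite(v2) || v2 > vmax_abort * vmax_abort) bad = true;
        if (S.kind[i] == KIND_FLUID && !std::isfinite(S.rho[i])) bad = true;
      }
      if (bad) { status = "unstable"; record(t, true); break; }
    }

    if (snapshot_every > 0 && (step % snapshot_every == 0))
      record(t, t >= settle_until);
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix fpos(n, 3), fvel(n, 3);
  NumericVector frho(n);
  for (int i = 0; i < n; ++i) {
    fpos(i, 0) = S.x[i]; fpos(i, 1) = S.y[i]; fpos(i, 2) = S.z[i];
    fvel(i, 0) = S.vx[i]; fvel(i, 1) = S.vy[i]; fvel(i, 2) = S.vz[i];
    frho[i] = S.rho[i];
  }
  List snaps(snap_t.size());
  for (size_t k = 0; k < snap_t.size(); ++k) {
    snaps[k] = List::create(_["time"] = snap_t[k], _["pos"] = snap_pos[k],
                            _["vel"] = snap_vel[k], _["dens"] = snap_rho[k]);
  }
  DataFrame diag = DataFrame::create(
    _["time"] = diag_t, _["kinetic_energy"] = diag_ke, _["v_max"] = diag_vmax,
    _["rho_min"] = diag_rhomin, _["rho_max"] = diag_rhomax,
    _["min_fluid_wall"] = diag_minfw);
  return List::create(_["status"] = status, _["time"] = t,
                      _["pos"] = fpos, _["vel"] = fvel, _["dens"] = frho,
                      _["snapshots"] = snaps, _["diagnostics"] = diag);
}

// ---------------------------------------------------------------------------
// Shepard-normalised SPH interpolation of a per-particle scalar field:
// f_i = sum_j (m_j / rho_j) f_j W_ij / sum_j (m_j / rho_j) W_ij
// (self-contribution included).

// [[Rcpp::export]]
NumericVector cpp_shepard(NumericMatrix pos, NumericVector val,
                          NumericVector mass, NumericVector dens, double h) {
  int n = pos.nrow();
  SimState S;
  S.n = n;
  S.x.resize(n); S.y.resize(n); S.z.resize(n);
  S.vx.assign(n, 0.0); S.vy.assign(n, 0.0); S.vz.assign(n, 0.0);
  S.m.resize(n); S.rho.resize(n); S.P.assign(n, 0.0);
  S.kind.assign(n, KIND_FLUID); S.seg.assign(n, 0);
  for (int i = 0; i < n; ++i) {
    S.x[i] = pos(i, 0); S.y[i] = pos(i, 1); S.z[i] = pos(i, 2);
    S.m[i] = mass[i]; S.rho[i] = dens[i];
  }
  double w0 = lucy_w(0.0, h);
  std::vector<double> num(n), den(n);
  for (int i = 0; i < n; ++i) {
    double v = S.m[i] / S.rho[i] * w0;
    num[i] = v * val[i];
    den[i] = v;
  }
  Periodic per;
  for_each_pair(S, h, per, [&](int i, int j, double, double, double, double r2) {
    double w = lucy_w(std::sqrt(r2), h);
    num[i] += S.m[j] / S.rho[j] * w * val[j];
    den[i] += S.m[j] / S.rho[j] * w;
    num[j] += S.m[i] / S.rho[i] * w * val[i];
    den[j] += S.m[i] / S.rho[i] * w;
  });
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = den[i] > 0 ? num[i] / den[i] : NA_REAL;
  return out;
}

// ---------------------------------------------------------------------------
// SPH estimate of the streamwise-velocity gradient (d vx / dy, d vx / dz) at
// fluid particles; wall particles contribute their own velocity (no-slip).

// [[Rcpp::export]]
NumericMatrix cpp_grad_vx(NumericMatrix pos, NumericVector vxv, NumericVector mass,
                          NumericVector dens, IntegerVector kind, double h,
                          bool corrected = true) {
  int n = pos.nrow();
  SimState S;
  S.n = n;
  S.x.resize(n); S.y.resize(n); S.z.resize(n);
  S.vx.assign(n, 0.0); S.vy.assign(n, 0.0); S.vz.assign(n, 0.0);
  S.m.resize(n); S.rho.resize(n); S.P.assign(n, 0.0);
  S.kind.resize(n); S.seg.assign(n, 0);
  for (int i = 0; i < n; ++i) {
    S.x[i] = pos(i, 0); S.y[i] = pos(i, 1); S.z[i] = pos(i, 2);
    S.m[i] = mass[i]; S.rho[i] = dens[i]; S.kind[i] = kind[i];
  }
  Periodic per;
  // raw difference-form gradient g3 and first-order moment matrix M so that
  // g3 = M grad(vx) holds exactly for linear fields; the corrected gradient
  // M^-1 g3 is therefore first-order consistent at any support and near
  // boundaries (Bonet-Lok style renormalisation)
  std::vector<double> g3(3 * n, 0.0), M(9 * n, 0.0);
  for_each_pair(S, h, per, [&](int i, int j, double dx, double dy, double dz, double r2) {
    if (r2 < 1e-24) return;
    double r = std::sqrt(r2);
    double dw = lucy_dw(r, h) / r;       // gradW_i = dw * (ri - rj)
    double dv = vxv[j] - vxv[i];
    // d = r_j - r_i = (-dx, -dy, -dz); gradW_i = dw * (dx, dy, dz)
    double gw[3] = {dw * dx, dw * dy, dw * dz};
    double d[3] = {-dx, -dy, -dz};
    if (S.kind[i] == KIND_FLUID) {
      double w = S.m[j] / S.rho[j];
      for (int a = 0; a < 3; ++a) {
        g3[3 * i + a] += w * dv * gw[a];
        for (int b = 0; b < 3; ++b) M[9 * i + 3 * a + b] += w * gw[a] * d[b];
      }
    }
    if (S.kind[j] == KIND_FLUID) {
      double w = S.m[i] / S.rho[i];
      // from j's viewpoint both gradW and d flip sign: products unchanged
      // except dv flips with gradW's sign flip -> dv * (-gw) * ... use
      // (vx_i - vx_j) = -dv and gradW_j = -gw
      for (int a = 0; a < 3; ++a) {
        g3[3 * j + a] += w * dv * gw[a];
        for (int b = 0; b < 3; ++b) M[9 * j + 3 * a + b] += w * gw[a] * d[b];
      }
    }
  });
  NumericMatrix g(n, 2);
  std::fill(g.begin(), g.end(), 0.0);
  for (int i = 0; i < n; ++i) {
    if (S.kind[i] != KIND_FLUID) continue;
    double *Mi = &M[9 * i], *gi = &g3[3 * i];
    if (corrected) {
      // solve Mi x = gi (3x3, Cramer)
      double a11 = Mi[0], a12 = Mi[1], a13 = Mi[2];
      double a21 = Mi[3], a22 = Mi[4], a23 = Mi[5];
      double a31 = Mi[6], a32 = Mi[7], a33 = Mi[8];
      double det = a11 * (a22 * a33 - a23 * a32)
                 - a12 * (a21 * a33 - a23 * a31)
                 + a13 * (a21 * a32 - a22 * a31);
      double scale = std::abs(a11) + std::abs(a22) + std::abs(a33);
      if (std::abs(det) > 1e-6 * scale * scale * scale + 1e-300) {
        double b1 = gi[0], b2 = gi[1], b3 = gi[2];
        double x2 = (a11 * (b2 * a33 - a23 * b3)
                   - b1 * (a21 * a33 - a23 * a31)
                   + a13 * (a21 * b3 - b2 * a31)) / det;
        double x3 = (a11 * (a22 * b3 - b2 * a32)
                   - a12 * (a21 * b3 - b2 * a31)
                   + b1 * (a21 * a32 - a22 * a31)) / det;
        g(i, 0) = x2; g(i, 1) = x3;
        continue;
      }
    }
    g(i, 0) = gi[1]; g(i, 1) = gi[2];
  }
  return g;
}
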