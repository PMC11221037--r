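// Shared geometry, RNG and physics helpers for the transport and analysis kernels.
#pragma once

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>

namespace iris {

// ---------------------------------------------------------------------------
// RNG: xoshiro256++ seeded via splitmix64.  Fully specified arithmetic so runs
// are reproducible across platforms; one independent stream per (seed, batch).
// ---------------------------------------------------------------------------
struct RNG {
  std::uint64_t s[4];

  static std::uint64_t splitmix(std::uint64_t& x) {
    std::uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  explicit RNG(std::uint64_t seed, std::uint64_t stream = 0) {
    std::uint64_t x = seed ^ (0x9E3779B97F4A7C15ULL * (stream + 1));
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }

  static std::uint64_t rotl(std::uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  std::uint64_t next() {
    const std::uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const std::uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in [0, 1)
  double u() { return (next() >> 11) * 0x1.0p-53; }
  // uniform in (0, 1]  (safe for log())
  double u_pos() { return ((next() >> 11) + 1) * 0x1.0p-53; }

  // standard normal pair, Box-Muller (explicit formula for determinism)
  void normal2(double& z1, double& z2) {
    double a = std::sqrt(-2.0 * std::log(u_pos()));
    double b = 6.283185307179586476925286766559 * u();
    z1 = a * std::cos(b);
    z2 = a * std::sin(b);
  }
};

struct Vec3 {
  double x, y, z;
};

inline Vec3 operator+(Vec3 a, Vec3 b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
inline Vec3 operator-(Vec3 a, Vec3 b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline Vec3 operator*(Vec3 a, double s) { return {a.x * s, a.y * s, a.z * s}; }
inline double dot(Vec3 a, Vec3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline double norm(Vec3 a) { return std::sqrt(dot(a, a)); }

// Build two unit vectors orthogonal to unit d.
inline void ortho_basis(Vec3 d, Vec3& a, Vec3& b) {
  if (std::fabs(d.z) < 0.99) {
    a = {-d.y, d.x, 0.0};
  } else {
    a = {0.0, -d.z, d.y};
  }
  double n = norm(a);
  a = a * (1.0 / n);
  b = {d.y * a.z - d.z * a.y, d.z * a.x - d.x * a.z, d.x * a.y - d.y * a.x};
}

// Rotate unit vector d by polar angle (cos = c) and azimuth psi about itself.
inline Vec3 rotate_direction(Vec3 d, double c, double psi) {
  double s = std::sqrt(std::max(0.0, 1.0 - c * c));
  Vec3 a, b;
  ortho_basis(d, a, b);
  Vec3 out = d * c + (a * std::cos(psi) + b * std::sin(psi)) * s;
  double n = norm(out);
  return out * (1.0 / n);
}

// ---------------------------------------------------------------------------
// Voxel grid: origin is the CENTER of voxel (0,0,0); voxel i spans
// origin + (i - 0.5) * spacing .. origin + (i + 0.5) * spacing.
// Linear index ix + nx*(iy + ny*iz) matches R's array layout.
// ---------------------------------------------------------------------------
struct Grid {
  int nx, ny, nz;
  double ox, oy, oz;       // center of voxel (0,0,0), mm
  double sx, sy, sz;       // spacing, mm
  const double* density;   // g/cm3
  const int* material;     // 0-based material index

  double lo(int a) const {
    return (a == 0 ? ox - 0.5 * sx : a == 1 ? oy - 0.5 * sy : oz - 0.5 * sz);
  }
  double hi(int a) const {
    return (a == 0 ? ox + (nx - 0.5) * sx
                   : a == 1 ? oy + (ny - 0.5) * sy : oz + (nz - 0.5) * sz);
  }

  bool inside(const Vec3& p) const {
    return p.x >= lo(0) && p.x < hi(0) && p.y >= lo(1) && p.y < hi(1) &&
           p.z >= lo(2) && p.z < hi(2);
  }

  // voxel index of a point assumed inside
  int index_of(const Vec3& p, int& ix, int& iy, int& iz) const {
    ix = (int)std::floor((p.x - (ox - 0.5 * sx)) / sx);
    iy = (int)std::floor((p.y - (oy - 0.5 * sy)) / sy);
    iz = (int)std::floor((p.z - (oz - 0.5 * sz)) / sz);
    ix = std::min(std::max(ix, 0), nx - 1);
    iy = std::min(std::max(iy, 0), ny - 1);
    iz = std::min(std::max(iz, 0), nz - 1);
    return ix + nx * (iy + ny * iz);
  }

  int lin(int ix, int iy, int iz) const { return ix + nx * (iy + ny * iz); }

  // Ray / box intersection: returns false on miss, else [t0, t1] along unit u.
  bool clip(const Vec3& p, const Vec3& u, double tmax_in, double& t0,
            double& t1) const {
    t0 = 0.0;
    t1 = tmax_in;
    const double pc[3] = {p.x, p.y, p.z};
    const double uc[3] = {u.x, u.y, u.z};
    for (int a = 0; a < 3; ++a) {
      double l = lo(a), h = hi(a);
      if (std::fabs(uc[a]) < 1e-14) {
        if (pc[a] < l || pc[a] >= h) return false;
      } else {
        double ta = (l - pc[a]) / uc[a];
        double tb = (h - pc[a]) / uc[a];
        if (ta > tb) std::swap(ta, tb);
        t0 = std::max(t0, ta);
        t1 = std::min(t1, tb);
      }
    }
    return t1 > t0 + 1e-12;
  }
};

inline Grid grid_from_list(const Rcpp::List& g,
                           const Rcpp::NumericVector& density,
                           const Rcpp::IntegerVector& material) {
  Grid gr;
  Rcpp::IntegerVector dims = g["dims"];
  Rcpp::NumericVector origin = g["origin"], spacing = g["spacing"];
  gr.nx = dims[0]; gr.ny = dims[1]; gr.nz = dims[2];
  gr.ox = origin[0]; gr.oy = origin[1]; gr.oz = origin[2];
  gr.sx = spacing[0]; gr.sy = spacing[1]; gr.sz = spacing[2];
  gr.density = density.begin();
  gr.material = material.begin();
  return gr;
}

// Water-equivalent (density-weighted) path length along a segment, exact
// voxel-boundary traversal.
inline double radiological_path(const Grid& g, Vec3 p0, Vec3 p1) {
  Vec3 d = p1 - p0;
  double L = norm(d);
  if (L <= 0.0) return 0.0;
  Vec3 u = d * (1.0 / L);
  double t0, t1;
  if (!g.clip(p0, u, L, t0, t1)) return 0.0;

  double t = t0;
  Vec3 ps = p0 + u * (t0 + 1e-9);
  int ix, iy, iz;
  g.index_of(ps, ix, iy, iz);

  const double uc[3] = {u.x, u.y, u.z};
  const double sp[3] = {g.sx, g.sy, g.sz};
  const double o[3] = {g.ox, g.oy, g.oz};
  const double pc[3] = {p0.x, p0.y, p0.z};
  int idx[3] = {ix, iy, iz};
  int step[3];
  double tMax[3], tDelta[3];
  for (int a = 0; a < 3; ++a) {
    if (uc[a] > 1e-14) {
      step[a] = 1;
      double bound = o[a] + (idx[a] + 0.5) * sp[a];
      tMax[a] = (bound - pc[a]) / uc[a];
      tDelta[a] = sp[a] / uc[a];
    } else if (uc[a] < -1e-14) {
      step[a] = -1;
      double bound = o[a] + (idx[a] - 0.5) * sp[a];
      tMax[a] = (bound - pc[a]) / uc[a];
      tDelta[a] = -sp[a] / uc[a];
    } else {
      step[a] = 0;
      tMax[a] = std::numeric_limits<double>::infinity();
      tDelta[a] = std::numeric_limits<double>::infinity();
    }
  }

  double acc = 0.0;
  const int nmax[3] = {g.nx, g.ny, g.nz};
  while (t < t1 - 1e-12) {
    int a = 0;
    if (tMax[1] < tMax[a]) a = 1;
    if (tMax[2] < tMax[a]) a = 2;
    double tnext = std::min(tMax[a], t1);
    double rho = g.density[g.lin(idx[0], idx[1], idx[2])];
    acc += rho * (tnext - t);
    t = tnext;
    if (tMax[a] >= t1) break;
    tMax[a] += tDelta[a];
    idx[a] += step[a];
    if (idx[a] < 0 || idx[a] >= nmax[a]) break;
  }
  return acc;
}

// ---------------------------------------------------------------------------
// Photon cross sections: per-material log(E) grids with log mass-attenuation
// components (photoelectric, Compton/incoherent, Rayleigh/coherent), cm2/g.
// Interpolation is linear in log-log space, clamped at the table ends.
// ---------------------------------------------------------------------------
struct XS {
  int nmat;
  std::vector<std::vector<double>> logE, lpe, lco, lra;

  void load(const Rcpp::List& tables) {
    nmat = tables.size();
    logE.resize(nmat); lpe.resize(nmat); lco.resize(nmat); lra.resize(nmat);
    for (int m = 0; m < nmat; ++m) {
      Rcpp::NumericMatrix t = tables[m];  // columns: logE, log_pe, log_co, log_ra
      int n = t.nrow();
      logE[m].assign(n, 0.0); lpe[m].assign(n, 0.0);
      lco[m].assign(n, 0.0); lra[m].assign(n, 0.0);
      for (int i = 0; i < n; ++i) {
        logE[m][i] = t(i, 0); lpe[m][i] = t(i, 1);
        lco[m][i] = t(i, 2); lra[m][i] = t(i, 3);
      }
    }
  }

  void mass_mu(int m, double E, double& pe, double& co, double& ra) const {
    const std::vector<double>& le = logE[m];
    double x = std::log(E);
    int n = (int)le.size();
    if (x <= le[0]) { pe = std::exp(lpe[m][0]); co = std::exp(lco[m][0]); ra = std::exp(lra[m][0]); return; }
    if (x >= le[n - 1]) { pe = std::exp(lpe[m][n-1]); co = std::exp(lco[m][n-1]); ra = std::exp(lra[m][n-1]); return; }
    int j = (int)(std::upper_bound(le.begin(), le.end(), x) - le.begin()) - 1;
    double w = (x - le[j]) / (le[j + 1] - le[j]);
    pe = std::exp(lpe[m][j] + w * (lpe[m][j + 1] - lpe[m][j]));
    co = std::exp(lco[m][j] + w * (lco[m][j + 1] - lco[m][j]));
    ra = std::exp(lra[m][j] + w * (lra[m][j + 1] - lra[m][j]));
  }
};

// Per-energy cache of mass attenuation per material plus the Woodcock majorant.
struct MuCache {
  const XS* xs;
  std::vector<double> maxdens;     // max density per material over the grid
  std::vector<double> pe, co, ra, tot;
  double E = -1.0, mu_max = 0.0;

  void init(const XS* x, const Grid& g) {
    xs = x;
    maxdens.assign(x->nmat, 0.0);
    long nvox = (long)g.nx * g.ny * g.nz;
    for (long i = 0; i < nvox; ++i) {
      int m = g.material[i];
      if (g.density[i] > maxdens[m]) maxdens[m] = g.density[i];
    }
    pe.assign(x->nmat, 0.0); co.assign(x->nmat, 0.0);
    ra.assign(x->nmat, 0.0); tot.assign(x->nmat, 0.0);
  }

  void update(double Enew) {
    if (Enew == E) return;
    E = Enew;
    mu_max = 0.0;
    for (int m = 0; m < xs->nmat; ++m) {
      xs->mass_mu(m, E, pe[m], co[m], ra[m]);
      tot[m] = pe[m] + co[m] + ra[m];
      double cand = tot[m] * maxdens[m];
      if (cand > mu_max) mu_max = cand;
    }
  }
};

// CSDA range table (mass range, g/cm2): range linear in log(E), clamped.
struct CSDA {
  std::vector<double> logE, R;
  void load(const Rcpp::NumericMatrix& t) {
    int n = t.nrow();
    logE.assign(n, 0.0); R.assign(n, 0.0);
    for (int i = 0; i < n; ++i) { logE[i] = t(i, 0); R[i] = t(i, 1); }
  }
  double range_g_cm2(double E) const {
    double x = std::log(E);
    int n = (int)logE.size();
    if (x <= logE[0]) return R[0];
    if (x >= logE[n - 1]) return R[n - 1];
    int j = (int)(std::upper_bound(logE.begin(), logE.end(), x) - logE.begin()) - 1;
    double w = (x - logE[j]) / (logE[j + 1] - logE[j]);
    return R[j] + w * (R[j + 1] - R[j]);
  }
};

// Klein-Nishina sampling of x = E'/E and cos(theta).  Envelope g(x) = 1/x + x
// on [1/(1+2a), 1]; acceptance ratio 1 - x sin^2(theta) / (1 + x^2).
inline void sample_klein_nishina(double E, RNG& rng, double& x_out,
                                 double& cos_out) {
  const double mec2 = 0.5109989;
  double a = E / mec2;
  double x0 = 1.0 / (1.0 + 2.0 * a);
  double A1 = std::log(1.0 / x0);
  double A2 = 0.5 * (1.0 - x0 * x0);
  for (;;) {
    double x;
    if (rng.u() * (A1 + A2) < A1) {
      x = x0 * std::exp(rng.u() * A1);
    } else {
      x = std::sqrt(x0 * x0 + rng.u() * (1.0 - x0 * x0));
    }
    double c = 1.0 - (1.0 - x) / (a * x);
    if (c < -1.0) c = -1.0;
    if (c > 1.0) c = 1.0;
    double sin2 = 1.0 - c * c;
    double accept = 1.0 - x * sin2 / (1.0 + x * x);
    if (rng.u() <= accept) {
      x_out = x;
      cos_out = c;
      return;
    }
  }
}

// Thomson angular sampling, pdf (3/8)(1 + cos^2).
inline double sample_thomson(RNG& rng) {
  for (;;) {
    double c = 2.0 * rng.u() - 1.0;
    if (rng.u() * 2.0 <= 1.0 + c * c) return c;
  }
}

// ---------------------------------------------------------------------------
// Condensed straight-ahead electron deposition with Highland-style lateral
// blur.  Deposits E/nsteps per step; step length is the density-scaled CSDA
// fraction.  Returns the escaped (weighted) energy; deposits go into tally.
// ---------------------------------------------------------------------------
inline double deposit_electron(const Grid& g, const CSDA& cs, Vec3 pos,
                               Vec3 dir, double E, double wt, int nsteps,
                               RNG& rng, double* tally, double* deposited) {
  const double mec2 = 0.5109989;
  const double X0 = 36.08;  // water radiation length, g/cm2
  double Rm = cs.range_g_cm2(E);   // g/cm2
  double step_g = Rm / nsteps;
  double escaped = 0.0;
  for (int k = 0; k < nsteps; ++k) {
    if (!g.inside(pos)) {
      escaped += (nsteps - k) * (E / nsteps) * wt;
      return escaped;
    }
    int ix, iy, iz;
    int v = g.index_of(pos, ix, iy, iz);
    double rho = g.density[v];
    double e_step = (E / nsteps) * wt;
    if (rho > 1e-6) {
      tally[v] += e_step;
      *deposited += e_step;
    } else {
      escaped += e_step;  // massless voxel cannot absorb energy
    }
    // density-scaled geometric step, mm (g/cm2 / g/cm3 = cm)
    double ds = 10.0 * step_g / std::max(rho, 1e-4);
    // Highland multiple-scattering angle at mid-step residual energy
    double Ek = E * (1.0 - (k + 0.5) / nsteps);
    double lat = 0.0;
    if (Ek > 1e-4) {
      double pc = std::sqrt(Ek * (Ek + 2.0 * mec2));  // MeV
      double beta = pc / (Ek + mec2);
      // Highland: theta0 [rad] = 13.6 MeV / (beta * pc) * sqrt(t / X0)
      double th0 = std::min(13.6 / (beta * pc) * std::sqrt(step_g / X0), 1.0);
      lat = ds * th0 / 1.7320508075688772;  // sigma of lateral offset per step
    }
    double z1, z2;
    rng.normal2(z1, z2);
    Vec3 a, b;
    ortho_basis(dir, a, b);
    pos = pos + dir * ds + a * (lat * z1) + b * (lat * z2);
  }
  return escaped;
}

}  // namespace iris
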