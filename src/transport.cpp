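// Monte Carlo photon transport (Woodcock tracking) and supporting samplers.
#include "engine.h"
using namespace Rcpp;
using namespace iris;

// Water-equivalent path length between two points, mm.
// [[Rcpp::export(name = ".rad_path_cpp")]]
double rad_path_cpp(List grid, NumericVector density, IntegerVector material,
                    NumericVector p0, NumericVector p1) {
  Grid g = grid_from_list(grid, density, material);
  return radiological_path(g, {p0[0], p0[1], p0[2]}, {p1[0], p1[1], p1[2]});
}

// Klein-Nishina samples at energy E: matrix (E_out, cos_theta).
// [[Rcpp::export(name = ".sample_compton_cpp")]]
NumericMatrix sample_compton_cpp(double E, int n, double seed) {
  RNG rng((std::uint64_t)seed, 101);
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double x, c;
    sample_klein_nishina(E, rng, x, c);
    out(i, 0) = E * x;
    out(i, 1) = c;
  }
  return out;
}

// Thomson angular samples (Rayleigh model), cos_theta.
// [[Rcpp::export(name = ".sample_thomson_cpp")]]
NumericVector sample_thomson_cpp(int n, double seed) {
  RNG rng((std::uint64_t)seed, 202);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sample_thomson(rng);
  return out;
}

// Woodcock free-path sampling from a fixed start/direction.  Returns the
// distance to the first real interaction (NA when the photon exits the grid).
// [[Rcpp::export(name = ".sample_free_path_cpp")]]
NumericVector sample_free_path_cpp(List grid, NumericVector density,
                                   IntegerVector material, List xs_tables,
                                   NumericVector pos, NumericVector dir,
                                   double E, int n, double seed) {
  Grid g = grid_from_list(grid, density, material);
  XS xs; xs.load(xs_tables);
  MuCache mc; mc.init(&xs, g); mc.update(E);
  RNG rng((std::uint64_t)seed, 303);
  NumericVector out(n);
  Vec3 p0 = {pos[0], pos[1], pos[2]};
  Vec3 u = {dir[0], dir[1], dir[2]};
  double un = norm(u); u = u * (1.0 / un);

  for (int i = 0; i < n; ++i) {
    Vec3 p = p0;
    double t = 0.0;
    if (!g.inside(p)) {
      double t0, t1;
      if (!g.clip(p, u, 1e9, t0, t1)) { out[i] = NA_REAL; continue; }
      t = t0 + 1e-9;
      p = p0 + u * t;
    }
    bool exited = false;
    if (mc.mu_max <= 0) exited = true;
    while (!exited) {
      double s = -std::log(rng.u_pos()) / mc.mu_max * 10.0;  // mu in 1/cm -> mm
      t += s;
      p = p0 + u * t;
      if (!g.inside(p)) { exited = true; break; }
      int ix, iy, iz;
      int v = g.index_of(p, ix, iy, iz);
      double mu_vox = mc.tot[g.material[v]] * g.density[v];
      if (rng.u() * mc.mu_max <= mu_vox) break;  // real interaction
    }
    out[i] = exited ? NA_REAL : t;
  }
  return out;
}

// Electron deposition for tests: returns per-voxel energy and escaped energy.
// [[Rcpp::export(name = ".deposit_electron_cpp")]]
List deposit_electron_cpp(List grid, NumericVector density,
                          IntegerVector material, NumericMatrix csda,
                          NumericVector pos, NumericVector dir, double E,
                          double wt, int nsteps, double seed) {
  Grid g = grid_from_list(grid, density, material);
  CSDA cs; cs.load(csda);
  RNG rng((std::uint64_t)seed, 404);
  long nvox = (long)g.nx * g.ny * g.nz;
  NumericVector tally(nvox);
  double dep = 0.0;
  Vec3 u = {dir[0], dir[1], dir[2]};
  double un = norm(u); u = u * (1.0 / un);
  double esc = deposit_electron(g, cs, {pos[0], pos[1], pos[2]}, u, E, wt,
                                nsteps, rng, tally.begin(), &dep);
  return List::create(_["energy"] = tally, _["deposited"] = dep,
                      _["escaped"] = esc);
}

namespace {

struct Tallies {
  double launched = 0.0, deposited = 0.0, escaped = 0.0;
};

void local_deposit(const Grid& g, const Vec3& p, double e, double wt,
                   double* tally, Tallies& tl) {
  int ix, iy, iz;
  int v = g.index_of(p, ix, iy, iz);
  if (g.density[v] > 1e-6) {
    tally[v] += e * wt;
    tl.deposited += e * wt;
  } else {
    tl.escaped += e * wt;
  }
}

void track_photon(const Grid& g, const XS& xs, MuCache& mc, const CSDA& cs,
                  Vec3 p, Vec3 u, double E, double wt, double cutoff,
                  int esteps, RNG& rng, double* tally, Tallies& tl) {
  const double mec2 = 0.5109989;
  const double TWO_PI = 6.283185307179586;

  if (!g.inside(p)) {
    double t0, t1;
    if (!g.clip(p, u, 1e9, t0, t1)) { tl.escaped += E * wt; return; }
    p = p + u * (t0 + 1e-9);
    if (!g.inside(p)) { tl.escaped += E * wt; return; }
  }

  for (;;) {
    if (E < cutoff) { local_deposit(g, p, E, wt, tally, tl); return; }
    mc.update(E);
    if (mc.mu_max <= 0.0) { tl.escaped += E * wt; return; }

    // Woodcock flight
    int v = -1, m = 0;
    for (;;) {
      double s = -std::log(rng.u_pos()) / mc.mu_max * 10.0;  // mm
      p = p + u * s;
      if (!g.inside(p)) { tl.escaped += E * wt; return; }
      int ix, iy, iz;
      v = g.index_of(p, ix, iy, iz);
      m = g.material[v];
      double mu_vox = mc.tot[m] * g.density[v];
      if (rng.u() * mc.mu_max <= mu_vox) break;
    }

    // interaction type from mass-coefficient components of this material
    double xi = rng.u() * mc.tot[m];
    if (xi < mc.pe[m]) {
      // photoelectric: all energy to a local electron along the photon direction
      if (E > cutoff) {
        double esc = deposit_electron(g, cs, p, u, E, wt, esteps, rng, tally,
                                      &tl.deposited);
        tl.escaped += esc;
      } else {
        local_deposit(g, p, E, wt, tally, tl);
      }
      return;
    } else if (xi < mc.pe[m] + mc.co[m]) {
      // Compton scattering
      double x, c;
      sample_klein_nishina(E, rng, x, c);
      double E1 = E * x;
      double Ee = E - E1;
      double psi = TWO_PI * rng.u();
      // electron polar angle: tan(phi) = 1 / ((1 + alpha) tan(theta/2))
      if (Ee > 1e-6) {
        double alpha = E / mec2;
        double t2 = std::sqrt(std::max(0.0, (1.0 - c) / (1.0 + c + 1e-12)));
        double ce = (1.0 + alpha) * t2 /
                    std::sqrt(1.0 + (1.0 + alpha) * (1.0 + alpha) * t2 * t2);
        Vec3 ue = rotate_direction(u, ce, psi + TWO_PI / 2.0);
        if (Ee > 1e-3) {
          double esc = deposit_electron(g, cs, p, ue, Ee, wt, esteps, rng,
                                        tally, &tl.deposited);
          tl.escaped += esc;
        } else {
          local_deposit(g, p, Ee, wt, tally, tl);
        }
      }
      u = rotate_direction(u, c, psi);
      E = E1;
      if (E < cutoff) { local_deposit(g, p, E, wt, tally, tl); return; }
    } else {
      // Rayleigh: direction change only (Thomson-shaped)
      double c = sample_thomson(rng);
      double psi = TWO_PI * rng.u();
      u = rotate_direction(u, c, psi);
    }
  }
}

}  // namespace

// One batch of one beam.  Particles are phase-space rows (E, x, y, u, v, w,
// wt) in the beam frame with the scoring plane at plane_z from the source;
// src/e1/e2/e3 define the beam frame in world coordinates (e3 = beam axis).
// Histories cycle through the particle list starting at start_index (0-based).
// [[Rcpp::export(name = ".mc_batch_cpp")]]
List mc_batch_cpp(List grid, NumericVector density, IntegerVector material,
                  List xs_tables, NumericMatrix csda, NumericMatrix particles,
                  double plane_z, NumericVector src, NumericVector e1,
                  NumericVector e2, NumericVector e3, int histories,
                  int start_index, double cutoff, int esteps, double seed,
                  double stream) {
  Grid g = grid_from_list(grid, density, material);
  XS xs; xs.load(xs_tables);
  CSDA cs; cs.load(csda);
  MuCache mc; mc.init(&xs, g);
  RNG rng((std::uint64_t)seed, (std::uint64_t)stream);

  long nvox = (long)g.nx * g.ny * g.nz;
  NumericVector tally(nvox);
  Tallies tl;

  Vec3 S = {src[0], src[1], src[2]};
  Vec3 E1 = {e1[0], e1[1], e1[2]};
  Vec3 E2 = {e2[0], e2[1], e2[2]};
  Vec3 E3 = {e3[0], e3[1], e3[2]};

  int np = particles.nrow();
  const double* PE = &particles(0, 0);
  const double* PX = &particles(0, 1);
  const double* PY = &particles(0, 2);
  const double* PU = &particles(0, 3);
  const double* PV = &particles(0, 4);
  const double* PW = &particles(0, 5);
  const double* PT = &particles(0, 6);

  for (int h = 0; h < histories; ++h) {
    int i = (int)(((long)start_index + h) % np);
    double wt = PT[i];
    double En = PE[i];
    tl.launched += En * wt;
    if (wt <= 0.0) continue;
    Vec3 p = S + E1 * PX[i] + E2 * PY[i] + E3 * plane_z;
    Vec3 u = E1 * PU[i] + E2 * PV[i] + E3 * PW[i];
    double un = norm(u);
    u = u * (1.0 / un);
    track_photon(g, xs, mc, cs, p, u, En, wt, cutoff, esteps, rng,
                 tally.begin(), tl);
  }

  return List::create(_["energy"] = tally, _["launched"] = tl.launched,
                      _["deposited"] = tl.deposited,
                      _["escaped"] = tl.escaped);
}

// Ray-tracing geometry per voxel for one beam: geometric depth below the
// beam-entry surface, water-equivalent (effective) depth, off-axis distance
// scaled to the SAD plane, and source-to-voxel distance.
// [[Rcpp::export(name = ".rt_geometry_cpp")]]
NumericMatrix rt_geometry_cpp(List grid, NumericVector density,
                              IntegerVector material, NumericVector src,
                              NumericVector axis, double sad,
                              double surface_density) {
  Grid g = grid_from_list(grid, density, material);
  Vec3 S = {src[0], src[1], src[2]};
  Vec3 ax = {axis[0], axis[1], axis[2]};
  double an = norm(ax);
  ax = ax * (1.0 / an);

  long nvox = (long)g.nx * g.ny * g.nz;
  NumericMatrix out(nvox, 4);

  for (int iz = 0; iz < g.nz; ++iz)
    for (int iy = 0; iy < g.ny; ++iy)
      for (int ix = 0; ix < g.nx; ++ix) {
        long v = g.lin(ix, iy, iz);
        Vec3 P = {g.ox + ix * g.sx, g.oy + iy * g.sy, g.oz + iz * g.sz};
        Vec3 d = P - S;
        double tP = norm(d);
        Vec3 u = d * (1.0 / tP);

        // march from grid entry to the voxel, find the beam-entry surface and
        // accumulate density beyond it
        double t0, t1;
        double t_surf = -1.0, deff = 0.0;
        if (g.clip(S, u, tP, t0, t1)) {
          double t = t0;
          Vec3 ps = S + u * (t0 + 1e-9);
          int jx, jy, jz;
          g.index_of(ps, jx, jy, jz);
          const double uc[3] = {u.x, u.y, u.z};
          const double sp[3] = {g.sx, g.sy, g.sz};
          const double o[3] = {g.ox, g.oy, g.oz};
          const double pc[3] = {S.x, S.y, S.z};
          int idx[3] = {jx, jy, jz};
          int step[3]; double tMax[3], tDelta[3];
          for (int a = 0; a < 3; ++a) {
            if (uc[a] > 1e-14) {
              step[a] = 1;
              tMax[a] = (o[a] + (idx[a] + 0.5) * sp[a] - pc[a]) / uc[a];
              tDelta[a] = sp[a] / uc[a];
            } else if (uc[a] < -1e-14) {
              step[a] = -1;
              tMax[a] = (o[a] + (idx[a] - 0.5) * sp[a] - pc[a]) / uc[a];
              tDelta[a] = -sp[a] / uc[a];
            } else {
              step[a] = 0;
              tMax[a] = std::numeric_limits<double>::infinity();
              tDelta[a] = std::numeric_limits<double>::infinity();
            }
          }
          const int nmax[3] = {g.nx, g.ny, g.nz};
          double tend = std::min(t1, tP);
          while (t < tend - 1e-12) {
            int a = 0;
            if (tMax[1] < tMax[a]) a = 1;
            if (tMax[2] < tMax[a]) a = 2;
            double tnext = std::min(tMax[a], tend);
            double rho = g.density[g.lin(idx[0], idx[1], idx[2])];
            if (t_surf < 0.0 && rho > surface_density) t_surf = t;
            if (t_surf >= 0.0) deff += rho * (tnext - std::max(t, t_surf));
            t = tnext;
            if (tMax[a] >= tend) break;
            tMax[a] += tDelta[a];
            idx[a] += step[a];
            if (idx[a] < 0 || idx[a] >= nmax[a]) break;
          }
        }

        double dgeom = (t_surf >= 0.0) ? (tP - t_surf) : NA_REAL;
        double axc = dot(d, ax);
        Vec3 perp = d - ax * axc;
        double rmeas = (axc > 1e-9) ? norm(perp) * (sad / axc) : 0.0;
        out(v, 0) = dgeom;
        out(v, 1) = (t_surf >= 0.0) ? deff : NA_REAL;
        out(v, 2) = rmeas;
        out(v, 3) = tP;
      }
  return out;
}
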