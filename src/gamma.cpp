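// 3D global gamma index: exhaustive search over an interpolated neighbourhood
// (step 0.1*dta, radius 3*dta by default), with offsets visited in order of
// increasing distance and an early exit once the distance term alone exceeds
// the current best gamma^2.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Offset {
  double dx, dy, dz;  // mm
  double r2norm;      // (|r| / dta)^2
};

inline bool trilinear(const double* ev, int nx, int ny, int nz, double fx,
                      double fy, double fz, double& out) {
  if (fx < 0.0 || fy < 0.0 || fz < 0.0 || fx > nx - 1.0 || fy > ny - 1.0 ||
      fz > nz - 1.0)
    return false;
  int ix = std::min((int)std::floor(fx), nx - 2 >= 0 ? nx - 2 : 0);
  int iy = std::min((int)std::floor(fy), ny - 2 >= 0 ? ny - 2 : 0);
  int iz = std::min((int)std::floor(fz), nz - 2 >= 0 ? nz - 2 : 0);
  if (nx == 1) ix = 0;
  if (ny == 1) iy = 0;
  if (nz == 1) iz = 0;
  double wx = fx - ix, wy = fy - iy, wz = fz - iz;
  int sx = (nx > 1) ? 1 : 0, sy = (ny > 1) ? nx : 0, sz = (nz > 1) ? nx * ny : 0;
  long b = ix + (long)nx * (iy + (long)ny * iz);
  double c00 = ev[b] * (1 - wx) + ev[b + sx] * wx;
  double c10 = ev[b + sy] * (1 - wx) + ev[b + sy + sx] * wx;
  double c01 = ev[b + sz] * (1 - wx) + ev[b + sz + sx] * wx;
  double c11 = ev[b + sz + sy] * (1 - wx) + ev[b + sz + sy + sx] * wx;
  double c0 = c00 * (1 - wy) + c10 * wy;
  double c1 = c01 * (1 - wy) + c11 * wy;
  out = c0 * (1 - wz) + c1 * wz;
  return true;
}

}  // namespace

// dose_tol and threshold are absolute dose values; dta in mm.
// [[Rcpp::export(name = ".gamma_cpp")]]
List gamma_cpp(NumericVector ref, NumericVector ev, IntegerVector dims,
               NumericVector spacing, double dose_tol, double dta,
               double threshold, double radius_factor, double step_factor) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long nvox = (long)nx * ny * nz;
  double step = step_factor * dta;
  int nstep = (int)std::ceil(radius_factor / step_factor);
  double rad2 = (radius_factor * dta) * (radius_factor * dta);

  std::vector<Offset> offs;
  offs.reserve(100000);
  for (int i = -nstep; i <= nstep; ++i)
    for (int j = -nstep; j <= nstep; ++j)
      for (int k = -nstep; k <= nstep; ++k) {
        double r2 = (double)(i * i + j * j + k * k) * step * step;
        if (r2 > rad2) continue;
        offs.push_back({i * step, j * step, k * step, r2 / (dta * dta)});
      }
  std::sort(offs.begin(), offs.end(),
            [](const Offset& a, const Offset& b) { return a.r2norm < b.r2norm; });

  NumericVector gamma(nvox, NA_REAL);
  LogicalVector mask(nvox);
  const double* R = ref.begin();
  const double* E = ev.begin();
  long npass = 0, neval = 0;

  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        long v = ix + (long)nx * (iy + (long)ny * iz);
        if (R[v] < threshold) { mask[v] = false; continue; }
        mask[v] = true;
        ++neval;
        double best = std::numeric_limits<double>::infinity();
        for (const Offset& o : offs) {
          if (o.r2norm >= best) break;
          double fx = ix + o.dx / spacing[0];
          double fy = iy + o.dy / spacing[1];
          double fz = iz + o.dz / spacing[2];
          double val;
          if (!trilinear(E, nx, ny, nz, fx, fy, fz, val)) continue;
          double dd = (val - R[v]) / dose_tol;
          double g2 = dd * dd + o.r2norm;
          if (g2 < best) best = g2;
        }
        gamma[v] = std::sqrt(best);
        if (gamma[v] <= 1.0) ++npass;
      }

  double pr = neval > 0 ? 100.0 * (double)npass / (double)neval : NA_REAL;
  return List::create(_["gamma"] = gamma, _["mask"] = mask,
                      _["pass_rate"] = pr, _["n_evaluated"] = (double)neval);
}
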