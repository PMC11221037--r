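// Brute-force gamma oracle: identical sampled-candidate definition as the
// optimized kernel but a plain dense scan -- no sorting, no early exit, its
// own interpolation code.  Used only by tests to validate gamma_3d.
#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// [[Rcpp::export(name = ".gamma_bruteforce_cpp")]]
List gamma_bruteforce_cpp(NumericVector ref, NumericVector ev,
                          IntegerVector dims, NumericVector spacing,
                          double dose_tol, double dta, double threshold,
                          double radius_factor, double step_factor) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long nvox = (long)nx * ny * nz;
  double step = step_factor * dta;
  int nstep = (int)std::ceil(radius_factor / step_factor);
  double rad2 = (radius_factor * dta) * (radius_factor * dta);

  NumericVector gamma(nvox, NA_REAL);
  LogicalVector mask(nvox);
  long npass = 0, neval = 0;

  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        long v = ix + (long)nx * (iy + (long)ny * iz);
        if (ref[v] < threshold) { mask[v] = false; continue; }
        mask[v] = true;
        ++neval;
        double best = std::numeric_limits<double>::infinity();

        for (int i = -nstep; i <= nstep; ++i)
          for (int j = -nstep; j <= nstep; ++j)
            for (int k = -nstep; k <= nstep; ++k) {
              double r2 = (double)(i * i + j * j + k * k) * step * step;
              if (r2 > rad2) continue;
              double fx = ix + (i * step) / spacing[0];
              double fy = iy + (j * step) / spacing[1];
              double fz = iz + (k * step) / spacing[2];
              if (fx < 0.0 || fy < 0.0 || fz < 0.0 || fx > nx - 1.0 ||
                  fy > ny - 1.0 || fz > nz - 1.0)
                continue;
              int ax = (int)std::floor(fx);
              int ay = (int)std::floor(fy);
              int az = (int)std::floor(fz);
              if (ax > nx - 2 && nx > 1) ax = nx - 2;
              if (ay > ny - 2 && ny > 1) ay = ny - 2;
              if (az > nz - 2 && nz > 1) az = nz - 2;
              if (nx == 1) ax = 0;
              if (ny == 1) ay = 0;
              if (nz == 1) az = 0;
              double wx = fx - ax, wy = fy - ay, wz = fz - az;
              int sx = (nx > 1) ? 1 : 0;
              int sy = (ny > 1) ? nx : 0;
              int sz = (nz > 1) ? nx * ny : 0;
              long b = ax + (long)nx * (ay + (long)ny * az);
              double c00 = ev[b] * (1 - wx) + ev[b + sx] * wx;
              double c10 = ev[b + sy] * (1 - wx) + ev[b + sy + sx] * wx;
              double c01 = ev[b + sz] * (1 - wx) + ev[b + sz + sx] * wx;
              double c11 = ev[b + sz + sy] * (1 - wx) + ev[b + sz + sy + sx] * wx;
              double val = (c00 * (1 - wy) + c10 * wy) * (1 - wz) +
                           (c01 * (1 - wy) + c11 * wy) * wz;
              double dd = (val - ref[v]) / dose_tol;
              double g2 = dd * dd + r2 / (dta * dta);
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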