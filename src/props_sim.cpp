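#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Sweep-accumulation kernel of the props forward model.
//
// For each scan position s the tilted sheet illuminates the oblique plane
// x = s + z*tan(phi) (plus across-sheet offsets when sheet_sigma > 0). Each
// illuminated sample lands on camera row u = z/cos(phi) + delta*tan(phi) +
// rate*s + q(s) + b; a synchronized rolling shutter keeps rows within
// halfwidth of u_sh(s) = rate*s + center + vu_tau. Accepted samples are
// splatted linearly into the frame at the sample-space row coordinate
// (u - b)/rate. Accumulation is scaled by ds/dx so that the total frame
// intensity matches the total volume intensity for a full-open, top-down
// acquisition (energy conservation), independent of the step size.
//
// vol is an R array with dim (nz, ny, nx), z fastest. halfwidth < 0 means a
// fully open shutter.
// [[Rcpp::export]]
NumericMatrix cpp_project_sweep(NumericVector vol, IntegerVector dims,
                                NumericVector voxel_size,
                                NumericVector origin,
                                NumericVector s_grid, NumericVector q_grid,
                                double rate, double offset_b,
                                double tilt_rad, double sheet_sigma,
                                double shutter_center, double halfwidth,
                                double vu_tau, double pixel_pitch,
                                double row_origin, int n_rows) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double dz = voxel_size[0], dx = voxel_size[2];
  const double z0 = origin[0], x0 = origin[2];
  const double tphi = std::tan(tilt_rad);
  const double cphi = std::cos(tilt_rad);
  const int ns = s_grid.size();
  const double ds = ns > 1 ? (s_grid[ns - 1] - s_grid[0]) / (ns - 1) : dx;

  NumericMatrix fr(n_rows, ny);

  std::vector<double> dlt(1, 0.0), wts(1, 1.0);
  if (sheet_sigma > 0) {
    const int m = 9;
    dlt.assign(m, 0.0);
    wts.assign(m, 0.0);
    double sw = 0.0;
    for (int j = 0; j < m; ++j) {
      double d = -3.0 * sheet_sigma + j * (6.0 * sheet_sigma / (m - 1));
      dlt[j] = d;
      wts[j] = std::exp(-d * d / (2.0 * sheet_sigma * sheet_sigma));
      sw += wts[j];
    }
    for (int j = 0; j < m; ++j) wts[j] /= sw;
  }
  const double scale0 = ds / dx;
  const double *v = REAL(vol);

  for (int k = 0; k < ns; ++k) {
    const double s = s_grid[k];
    const double q = q_grid[k];
    const double ush = rate * s + shutter_center + vu_tau;
    for (int iz = 0; iz < nz; ++iz) {
      const double z = z0 + iz * dz;
      for (size_t j = 0; j < dlt.size(); ++j) {
        const double x = s + z * tphi + dlt[j] / cphi;
        const double u = z / cphi + dlt[j] * tphi + rate * s + q + offset_b;
        if (halfwidth >= 0 && std::fabs(u - ush) > halfwidth) continue;
        const double fx = (x - x0) / dx;
        if (fx < 0.0 || fx > nx - 1) continue;
        int ix0 = (int)std::floor(fx);
        double ax = fx - ix0;
        int ix1 = ix0 + 1 < nx ? ix0 + 1 : ix0;
        const double p = ((u - offset_b) / rate - row_origin) / pixel_pitch;
        if (p < 0.0 || p > n_rows - 1) continue;
        int ip0 = (int)std::floor(p);
        double ap = p - ip0;
        int ip1 = ip0 + 1 < n_rows ? ip0 + 1 : ip0;
        const double w = scale0 * wts[j];
        const double *plane0 = v + (size_t)iz + (size_t)nz * (size_t)ny * ix0;
        const double *plane1 = v + (size_t)iz + (size_t)nz * (size_t)ny * ix1;
        for (int iy = 0; iy < ny; ++iy) {
      const double val = (1.0 - ax) * plane0[(size_t)nz * iy] +
                             ax * plane1[(size_t)nz * iy];
          if (val == 0.0) continue;
          fr(ip0, iy) += (1.0 - ap) * w * val;
          fr(ip1, iy) += ap * w * val;
        }
      }
    }
  }
  return fr;
}
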