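#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <array>
using namespace Rcpp;

// 3D scalar fields are stored as R arrays (x fastest), addressed here with
// 0-based voxel indices.  All displacement components are in mm on the grid
// of the fixed image; conversion to voxel units uses the per-axis spacing.

static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

static std::vector<double> gauss_kernel(double sigma) {
  int r = (int)std::ceil(3.0 * sigma);
  if (sigma <= 0 || r < 1) return std::vector<double>(1, 1.0);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)(i * i) / (sigma * sigma));
    s += k[i + r];
  }
  for (size_t i = 0; i < k.size(); ++i) k[i] /= s;
  return k;
}

// separable convolution along one axis, reflected boundary
static void conv_axis(std::vector<double> &a, int nx, int ny, int nz,
                      const std::vector<double> &k, int axis) {
  int r = ((int)k.size() - 1) / 2;
  if (r == 0) return;
  std::vector<double> out(a.size());
  int n[3] = {nx, ny, nz};
  int nax = n[axis];
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int idx[3] = {x, y, z};
        double acc = 0.0;
        for (int t = -r; t <= r; ++t) {
          int j[3] = {x, y, z};
          j[axis] = reflect_idx(idx[axis] + t, nax);
          acc += k[t + r] * a[(size_t)j[0] + (size_t)nx * (j[1] + (size_t)ny * j[2])];
        }
        out[(size_t)x + (size_t)nx * (y + (size_t)ny * z)] = acc;
      }
  a.swap(out);
}

// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector arr, IntegerVector dim, NumericVector sigma_vox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> a(arr.begin(), arr.end());
  for (int ax = 0; ax < 3; ++ax) {
    std::vector<double> k = gauss_kernel(sigma_vox[ax]);
    conv_axis(a, nx, ny, nz, k, ax);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

static inline double at(const double *a, int nx, int ny, int nz, int x, int y, int z) {
  if (x < 0) x = 0; if (x >= nx) x = nx - 1;
  if (y < 0) y = 0; if (y >= ny) y = ny - 1;
  if (z < 0) z = 0; if (z >= nz) z = nz - 1;
  return a[(size_t)x + (size_t)nx * (y + (size_t)ny * z)];
}

// trilinear sample at continuous 0-based voxel coordinates; clamp=false uses
// a constant background outside the grid, clamp=true extends edge values
static inline double sample_tri(const double *a, int nx, int ny, int nz,
                                double x, double y, double z,
                                bool clamp, double background) {
  const double eps = 1e-6;  // voxel centers on the boundary stay in-field
  if (!clamp && (x < -eps || y < -eps || z < -eps ||
                 x > nx - 1 + eps || y > ny - 1 + eps || z > nz - 1 + eps))
    return background;
  if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
  if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
  if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double c000 = at(a, nx, ny, nz, x0, y0, z0),     c100 = at(a, nx, ny, nz, x0 + 1, y0, z0);
  double c010 = at(a, nx, ny, nz, x0, y0 + 1, z0), c110 = at(a, nx, ny, nz, x0 + 1, y0 + 1, z0);
  double c001 = at(a, nx, ny, nz, x0, y0, z0 + 1), c101 = at(a, nx, ny, nz, x0 + 1, y0, z0 + 1);
  double c011 = at(a, nx, ny, nz, x0, y0 + 1, z0 + 1), c111 = at(a, nx, ny, nz, x0 + 1, y0 + 1, z0 + 1);
  double c00 = c000 * (1 - fx) + c100 * fx;
  double c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx;
  double c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector arr, IntegerVector dim,
                            NumericVector x, NumericVector y, NumericVector z,
                            double background, bool clamp) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = x.size();
  NumericVector out(n);
  const double *a = arr.begin();
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = sample_tri(a, nx, ny, nz, x[i], y[i], z[i], clamp, background);
  return out;
}

// One pyramid level of optical-flow (demons-type) iteration.  fixed/moving on
// the same grid; u* in mm; sigma_vox smooths the field after every update.
// [[Rcpp::export]]
List cpp_flow_level(NumericVector fixed, NumericVector moving, IntegerVector dim,
                    NumericVector spacing,
                    NumericVector ux0, NumericVector uy0, NumericVector uz0,
                    int iterations, NumericVector sigma_update_vox,
                    NumericVector sigma_field_vox,
                    double tol_mm, double max_step_mm) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  double kappa = (sx + sy + sz) / 3.0;
  double kappa2 = kappa * kappa;
  std::vector<double> ux(ux0.begin(), ux0.end());
  std::vector<double> uy(uy0.begin(), uy0.end());
  std::vector<double> uz(uz0.begin(), uz0.end());
  std::vector<double> warped(n), dux(n), duy(n), duz(n);
  const double *F = fixed.begin();
  const double *M = moving.begin();
  std::vector<double> kux = gauss_kernel(sigma_update_vox[0]);
  std::vector<double> kuy = gauss_kernel(sigma_update_vox[1]);
  std::vector<double> kuz = gauss_kernel(sigma_update_vox[2]);
  std::vector<double> kfx = gauss_kernel(sigma_field_vox[0]);
  std::vector<double> kfy = gauss_kernel(sigma_field_vox[1]);
  std::vector<double> kfz = gauss_kernel(sigma_field_vox[2]);
  bool smooth_update = sigma_update_vox[0] > 0 || sigma_update_vox[1] > 0 ||
    sigma_update_vox[2] > 0;
  bool smooth_field = sigma_field_vox[0] > 0 || sigma_field_vox[1] > 0 ||
    sigma_field_vox[2] > 0;

  double mean_update = R_PosInf;
  int it = 0;
  for (it = 0; it < iterations; ++it) {
    // warp moving by current field
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          size_t i = (size_t)x + (size_t)nx * (y + (size_t)ny * z);
          warped[i] = sample_tri(M, nx, ny, nz,
                                 x + ux[i] / sx, y + uy[i] / sy, z + uz[i] / sz,
                                 true, 0.0);
        }
    // force from brightness difference and warped-image gradient
    double upd = 0.0;
    const double *W = warped.data();
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          size_t i = (size_t)x + (size_t)nx * (y + (size_t)ny * z);
          // no data support on the outermost layer (clamped sampling and
          // one-sided content); a zero update there keeps field-of-view-edge
          // artifacts from diffusing inward
          if (x == 0 || y == 0 || z == 0 || x == nx - 1 || y == ny - 1 || z == nz - 1) {
            dux[i] = 0; duy[i] = 0; duz[i] = 0;
            continue;
          }
          double diff = W[i] - F[i];
          double gx = (at(W, nx, ny, nz, x + 1, y, z) - at(W, nx, ny, nz, x - 1, y, z)) / (2.0 * sx);
          double gy = (at(W, nx, ny, nz, x, y + 1, z) - at(W, nx, ny, nz, x, y - 1, z)) / (2.0 * sy);
          double gz = (at(W, nx, ny, nz, x, y, z + 1) - at(W, nx, ny, nz, x, y, z - 1)) / (2.0 * sz);
          double g2 = gx * gx + gy * gy + gz * gz;
          double denom = g2 + diff * diff / kappa2;
          double dx = 0, dy = 0, dz2 = 0;
          if (denom > 1e-12) {
            double f = -diff / denom;
            dx = f * gx; dy = f * gy; dz2 = f * gz;
            double mag = std::sqrt(dx * dx + dy * dy + dz2 * dz2);
            if (mag > max_step_mm) {
              double sc = max_step_mm / mag;
              dx *= sc; dy *= sc; dz2 *= sc;
            }
          }
          dux[i] = dx; duy[i] = dy; duz[i] = dz2;
          upd += std::sqrt(dx * dx + dy * dy + dz2 * dz2);
        }
    mean_update = upd / (double)n;
    // gradient-smoothness regularisation: fluid-like smoothing of the update
    // plus optional diffusion-like smoothing of the accumulated field
    if (smooth_update) {
      conv_axis(dux, nx, ny, nz, kux, 0); conv_axis(dux, nx, ny, nz, kuy, 1); conv_axis(dux, nx, ny, nz, kuz, 2);
      conv_axis(duy, nx, ny, nz, kux, 0); conv_axis(duy, nx, ny, nz, kuy, 1); conv_axis(duy, nx, ny, nz, kuz, 2);
      conv_axis(duz, nx, ny, nz, kux, 0); conv_axis(duz, nx, ny, nz, kuy, 1); conv_axis(duz, nx, ny, nz, kuz, 2);
    }
    for (size_t i = 0; i < n; ++i) { ux[i] += dux[i]; uy[i] += duy[i]; uz[i] += duz[i]; }
    if (smooth_field) {
      conv_axis(ux, nx, ny, nz, kfx, 0); conv_axis(ux, nx, ny, nz, kfy, 1); conv_axis(ux, nx, ny, nz, kfz, 2);
      conv_axis(uy, nx, ny, nz, kfx, 0); conv_axis(uy, nx, ny, nz, kfy, 1); conv_axis(uy, nx, ny, nz, kfz, 2);
      conv_axis(uz, nx, ny, nz, kfx, 0); conv_axis(uz, nx, ny, nz, kfy, 1); conv_axis(uz, nx, ny, nz, kfz, 2);
    }
    if (mean_update < tol_mm) { ++it; break; }
  }
  NumericVector oux(ux.begin(), ux.end()), ouy(uy.begin(), uy.end()), ouz(uz.begin(), uz.end());
  oux.attr("dim") = dim; ouy.attr("dim") = dim; ouz.attr("dim") = dim;
  return List::create(_["ux"] = oux, _["uy"] = ouy, _["uz"] = ouz,
                      _["iterations"] = it, _["mean_update"] = mean_update,
                      _["converged"] = (mean_update < tol_mm));
}

// forward (push) trilinear splat of per-voxel weights onto the same grid,
// displaced by the field in mm
// [[Rcpp::export]]
NumericVector cpp_splat(NumericVector weights, IntegerVector dim, NumericVector spacing,
                        NumericVector ux, NumericVector uy, NumericVector uz) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector out((R_xlen_t)n);
  out.attr("dim") = dim;
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        size_t i = (size_t)x + (size_t)nx * (y + (size_t)ny * z);
        double w = weights[i];
        if (w == 0.0) continue;
        double px = x + ux[i] / sx, py = y + uy[i] / sy, pz = z + uz[i] / sz;
        int x0 = (int)std::floor(px), y0 = (int)std::floor(py), z0 = (int)std::floor(pz);
        double fx = px - x0, fy = py - y0, fz = pz - z0;
        for (int dz = 0; dz <= 1; ++dz)
          for (int dy = 0; dy <= 1; ++dy)
            for (int dx = 0; dx <= 1; ++dx) {
              int X = x0 + dx, Y = y0 + dy, Z = z0 + dz;
              if (X < 0 || Y < 0 || Z < 0 || X >= nx || Y >= ny || Z >= nz) continue;
              double wt = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
              out[(size_t)X + (size_t)nx * (Y + (size_t)ny * Z)] += w * wt;
            }
      }
  return out;
}

// binary dilation with a spherical structuring element of radius_mm
// [[Rcpp::export]]
LogicalVector cpp_dilate(LogicalVector mask, IntegerVector dim, NumericVector spacing,
                         double radius_mm) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  int rx = (int)std::floor(radius_mm / sx), ry = (int)std::floor(radius_mm / sy),
      rz = (int)std::floor(radius_mm / sz);
  std::vector<std::array<int, 3> > offs;
  for (int dz = -rz; dz <= rz; ++dz)
    for (int dy = -ry; dy <= ry; ++dy)
      for (int dx = -rx; dx <= rx; ++dx) {
        double d2 = dx * sx * dx * sx + dy * sy * dy * sy + dz * sz * dz * sz;
        if (d2 <= radius_mm * radius_mm) offs.push_back({dx, dy, dz});
      }
  LogicalVector out((R_xlen_t)nx * ny * nz);
  out.attr("dim") = dim;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        size_t i = (size_t)x + (size_t)nx * (y + (size_t)ny * z);
        if (!mask[i]) continue;
        for (size_t k = 0; k < offs.size(); ++k) {
          int X = x + offs[k][0], Y = y + offs[k][1], Z = z + offs[k][2];
          if (X < 0 || Y < 0 || Z < 0 || X >= nx || Y >= ny || Z >= nz) continue;
          out[(size_t)X + (size_t)nx * (Y + (size_t)ny * Z)] = true;
        }
      }
  return out;
}
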