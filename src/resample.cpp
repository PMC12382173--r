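#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear sample at continuous 0-based voxel coordinate (x, y, z).
// Coordinates up to half a voxel outside the grid are clamped; anything
// further out returns `fill`.
static inline double sample_trilinear(const double *v, int nx, int ny, int nz,
                                      double x, double y, double z,
                                      double fill) {
  if (x < -0.5 || y < -0.5 || z < -0.5 ||
      x > nx - 0.5 || y > ny - 0.5 || z > nz - 0.5)
    return fill;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  int x1 = x0 + 1, y1 = y0 + 1, z1 = z0 + 1;
  // clamp to valid indices (handles the half-voxel border band)
  if (x0 < 0) { x0 = 0; }  if (x1 > nx - 1) { x1 = nx - 1; }
  if (y0 < 0) { y0 = 0; }  if (y1 > ny - 1) { y1 = ny - 1; }
  if (z0 < 0) { z0 = 0; }  if (z1 > nz - 1) { z1 = nz - 1; }
  if (x0 > nx - 1) x0 = nx - 1;  if (x1 < 0) x1 = 0;
  if (y0 > ny - 1) y0 = ny - 1;  if (y1 < 0) y1 = 0;
  if (z0 > nz - 1) z0 = nz - 1;  if (z1 < 0) z1 = 0;
  size_t nxy = (size_t)nx * ny;
  double c000 = v[x0 + (size_t)nx * y0 + nxy * z0];
  double c100 = v[x1 + (size_t)nx * y0 + nxy * z0];
  double c010 = v[x0 + (size_t)nx * y1 + nxy * z0];
  double c110 = v[x1 + (size_t)nx * y1 + nxy * z0];
  double c001 = v[x0 + (size_t)nx * y0 + nxy * z1];
  double c101 = v[x1 + (size_t)nx * y0 + nxy * z1];
  double c011 = v[x0 + (size_t)nx * y1 + nxy * z1];
  double c111 = v[x1 + (size_t)nx * y1 + nxy * z1];
  double c00 = c000 * (1 - fx) + c100 * fx;
  double c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx;
  double c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

static inline double sample_nearest(const double *v, int nx, int ny, int nz,
                                    double x, double y, double z, double fill) {
  int xi = (int)std::lround(x), yi = (int)std::lround(y), zi = (int)std::lround(z);
  if (xi < 0 || yi < 0 || zi < 0 || xi > nx - 1 || yi > ny - 1 || zi > nz - 1)
    return fill;
  return v[xi + (size_t)nx * yi + (size_t)nx * ny * zi];
}

// Resample `vol` (dims `dim_in`) onto an output grid of dims `dim_out`.
// `map` is a 3x4 matrix sending 0-based output voxel indices (i, j, k)
// to continuous 0-based input voxel coordinates.
// [[Rcpp::export]]
NumericVector resample_affine_cpp(NumericVector vol, IntegerVector dim_in,
                                  IntegerVector dim_out, NumericMatrix map,
                                  double fill, bool nearest) {
  int nx = dim_in[0], ny = dim_in[1], nz = dim_in[2];
  int ox = dim_out[0], oy = dim_out[1], oz = dim_out[2];
  const double *v = REAL(vol);
  NumericVector out((R_xlen_t)ox * oy * oz);
  double *o = REAL(out);
  double m00 = map(0, 0), m01 = map(0, 1), m02 = map(0, 2), m03 = map(0, 3);
  double m10 = map(1, 0), m11 = map(1, 1), m12 = map(1, 2), m13 = map(1, 3);
  double m20 = map(2, 0), m21 = map(2, 1), m22 = map(2, 2), m23 = map(2, 3);
  size_t idx = 0;
  for (int k = 0; k < oz; ++k) {
    for (int j = 0; j < oy; ++j) {
      double xb = m01 * j + m02 * k + m03;
      double yb = m11 * j + m12 * k + m13;
      double zb = m21 * j + m22 * k + m23;
      for (int i = 0; i < ox; ++i, ++idx) {
        double x = m00 * i + xb, y = m10 * i + yb, z = m20 * i + zb;
        o[idx] = nearest ? sample_nearest(v, nx, ny, nz, x, y, z, fill)
                         : sample_trilinear(v, nx, ny, nz, x, y, z, fill);
      }
    }
  }
  return out;
}

// Separable 1-D convolution along `axis` (0, 1 or 2) with reflect padding.
// [[Rcpp::export]]
NumericVector conv1d_axis_cpp(NumericVector vol, IntegerVector dims,
                              NumericVector kernel, int axis) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int kl = kernel.size(), half = kl / 2;
  const double *v = REAL(vol);
  const double *kw = REAL(kernel);
  NumericVector out((R_xlen_t)nx * ny * nz);
  double *o = REAL(out);
  size_t nxy = (size_t)nx * ny;
  int n_axis = axis == 0 ? nx : (axis == 1 ? ny : nz);
  size_t stride = axis == 0 ? 1 : (axis == 1 ? (size_t)nx : nxy);
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        int pos = axis == 0 ? i : (axis == 1 ? j : k);
        size_t base = i + (size_t)nx * j + nxy * k;
        double acc = 0.0;
        for (int t = 0; t < kl; ++t) {
          int p = pos + t - half;
          if (p < 0) p = -p;                          // reflect
          if (p > n_axis - 1) p = 2 * (n_axis - 1) - p;
          long long off = (long long)base + (long long)(p - pos) * (long long)stride;
          acc += kw[t] * v[off];
        }
        o[base] = acc;
      }
    }
  }
  return out;
}
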