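#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Affine resampling of a 3-D volume.
//
// M is a 4x4 matrix mapping 0-based OUTPUT voxel indices to 0-based INPUT
// voxel coordinates (continuous). method: 0 = trilinear, 1 = nearest.
// Voxel centers sit at integer indices; samples outside the input grid are 0.
// Coordinates within 1e-6 of an integer are snapped so that integer-voxel
// shifts reproduce array values bit-exactly.
// [[Rcpp::export]]
NumericVector resample_affine_cpp(NumericVector src, IntegerVector src_dim,
                                  NumericMatrix M, IntegerVector out_dim,
                                  int method) {
  const int nx = src_dim[0], ny = src_dim[1], nz = src_dim[2];
  const int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
  const double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
  const double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);
  const double *s = src.begin();
  double *o = out.begin();
  const R_xlen_t sxy = (R_xlen_t)nx * ny;

  R_xlen_t idx = 0;
  for (int k = 0; k < oz; ++k) {
    for (int j = 0; j < oy; ++j) {
      double xb = m01 * j + m02 * k + m03;
      double yb = m11 * j + m12 * k + m13;
      double zb = m21 * j + m22 * k + m23;
      for (int i = 0; i < ox; ++i, ++idx) {
        double x = m00 * i + xb;
        double y = m10 * i + yb;
        double z = m20 * i + zb;
        // snap near-integer coordinates
        double rx = std::round(x), ry = std::round(y), rz = std::round(z);
        if (std::fabs(x - rx) < 1e-6) x = rx;
        if (std::fabs(y - ry) < 1e-6) y = ry;
        if (std::fabs(z - rz) < 1e-6) z = rz;
        if (method == 1) {
          int xi = (int)std::round(x), yi = (int)std::round(y),
              zi = (int)std::round(z);
          if (xi < 0 || yi < 0 || zi < 0 || xi >= nx || yi >= ny || zi >= nz) {
            o[idx] = 0.0;
          } else {
            o[idx] = s[xi + (R_xlen_t)yi * nx + (R_xlen_t)zi * sxy];
          }
        } else {
          if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 ||
              z > nz - 1) {
            o[idx] = 0.0;
            continue;
          }
          int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
              z0 = (int)std::floor(z);
          double fx = x - x0, fy = y - y0, fz = z - z0;
          int x1 = (fx > 0.0) ? x0 + 1 : x0;
          int y1 = (fy > 0.0) ? y0 + 1 : y0;
          int z1 = (fz > 0.0) ? z0 + 1 : z0;
          const double c000 = s[x0 + (R_xlen_t)y0 * nx + (R_xlen_t)z0 * sxy];
          const double c100 = s[x1 + (R_xlen_t)y0 * nx + (R_xlen_t)z0 * sxy];
          const double c010 = s[x0 + (R_xlen_t)y1 * nx + (R_xlen_t)z0 * sxy];
          const double c110 = s[x1 + (R_xlen_t)y1 * nx + (R_xlen_t)z0 * sxy];
          const double c001 = s[x0 + (R_xlen_t)y0 * nx + (R_xlen_t)z1 * sxy];
          const double c101 = s[x1 + (R_xlen_t)y0 * nx + (R_xlen_t)z1 * sxy];
          const double c011 = s[x0 + (R_xlen_t)y1 * nx + (R_xlen_t)z1 * sxy];
          const double c111 = s[x1 + (R_xlen_t)y1 * nx + (R_xlen_t)z1 * sxy];
          double c00 = c000 + (c100 - c000) * fx;
          double c10 = c010 + (c110 - c010) * fx;
          double c01 = c001 + (c101 - c001) * fx;
          double c11 = c011 + (c111 - c011) * fx;
          double c0 = c00 + (c10 - c00) * fy;
          double c1 = c01 + (c11 - c01) * fy;
          o[idx] = c0 + (c1 - c0) * fz;
        }
      }
    }
  }
  return out;
}

// Sum of squared differences between an affine-resampled volume and a
// fixed volume on the fixed grid, without materialising the resampled
// array (the registration hot loop).
// [[Rcpp::export]]
double ssd_affine_cpp(NumericVector src, IntegerVector src_dim,
                      NumericMatrix M, NumericVector fixed,
                      IntegerVector out_dim) {
  const int nx = src_dim[0], ny = src_dim[1], nz = src_dim[2];
  const int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  const double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
  const double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
  const double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);
  const double *s = src.begin();
  const double *f = fixed.begin();
  const R_xlen_t sxy = (R_xlen_t)nx * ny;
  double acc = 0.0;
  R_xlen_t idx = 0;
  for (int k = 0; k < oz; ++k) {
    for (int j = 0; j < oy; ++j) {
      double xb = m01 * j + m02 * k + m03;
      double yb = m11 * j + m12 * k + m13;
      double zb = m21 * j + m22 * k + m23;
      for (int i = 0; i < ox; ++i, ++idx) {
        double x = m00 * i + xb;
        double y = m10 * i + yb;
        double z = m20 * i + zb;
        double v = 0.0;
        if (!(x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 ||
              z > nz - 1)) {
          int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
              z0 = (int)std::floor(z);
          double fx = x - x0, fy = y - y0, fz = z - z0;
          int x1 = (fx > 0.0) ? x0 + 1 : x0;
          int y1 = (fy > 0.0) ? y0 + 1 : y0;
          int z1 = (fz > 0.0) ? z0 + 1 : z0;
          const double c000 = s[x0 + (R_xlen_t)y0 * nx + (R_xlen_t)z0 * sxy];
          const double c100 = s[x1 + (R_xlen_t)y0 * nx + (R_xlen_t)z0 * sxy];
          const double c010 = s[x0 + (R_xlen_t)y1 * nx + (R_xlen_t)z0 * sxy];
          const double c110 = s[x1 + (R_xlen_t)y1 * nx + (R_xlen_t)z0 * sxy];
          const double c001 = s[x0 + (R_xlen_t)y0 * nx + (R_xlen_t)z1 * sxy];
          const double c101 = s[x1 + (R_xlen_t)y0 * nx + (R_xlen_t)z1 * sxy];
          const double c011 = s[x0 + (R_xlen_t)y1 * nx + (R_xlen_t)z1 * sxy];
          const double c111 = s[x1 + (R_xlen_t)y1 * nx + (R_xlen_t)z1 * sxy];
          double c00 = c000 + (c100 - c000) * fx;
          double c10 = c010 + (c110 - c010) * fx;
          double c01 = c001 + (c101 - c001) * fx;
          double c11 = c011 + (c111 - c011) * fx;
          double c0 = c00 + (c10 - c00) * fy;
          double c1 = c01 + (c11 - c01) * fy;
          v = c0 + (c1 - c0) * fz;
        }
        double d = v - f[idx];
        acc += d * d;
      }
    }
  }
  return acc;
}
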