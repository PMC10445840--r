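// Dense interpolation and B-spline lattice kernels.
// These are the inner loops of resampling and FFD registration; everything
// else stays in R.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline R_xlen_t idx3(int i, int j, int k, int n1, int n2) {
  return (R_xlen_t)i + (R_xlen_t)n1 * ((R_xlen_t)j + (R_xlen_t)n2 * k);
}

// Trilinear interpolation of a 3D array at continuous 0-based voxel
// coordinates. Points with any coordinate outside [0, n-1] return `fill`.
// [[Rcpp::export]]
NumericVector sample_trilinear_cpp(NumericVector arr, IntegerVector dim,
                                   NumericMatrix vox, double fill) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t m = vox.nrow();
  NumericVector out(m);
  for (R_xlen_t p = 0; p < m; ++p) {
    double x = vox(p, 0), y = vox(p, 1), z = vox(p, 2);
    // tolerate sub-voxel rounding error at the grid boundary
    const double eps = 1e-6;
    if (!(x >= -eps && x <= n1 - 1.0 + eps && y >= -eps &&
          y <= n2 - 1.0 + eps && z >= -eps && z <= n3 - 1.0 + eps)) {
      out[p] = fill;
      continue;
    }
    if (x < 0.0) x = 0.0;
    if (x > n1 - 1.0) x = n1 - 1.0;
    if (y < 0.0) y = 0.0;
    if (y > n2 - 1.0) y = n2 - 1.0;
    if (z < 0.0) z = 0.0;
    if (z > n3 - 1.0) z = n3 - 1.0;
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y),
        k0 = (int)std::floor(z);
    if (i0 > n1 - 2) i0 = n1 - 2;
    if (j0 > n2 - 2) j0 = n2 - 2;
    if (k0 > n3 - 2) k0 = n3 - 2;
    if (i0 < 0) i0 = 0;
    if (j0 < 0) j0 = 0;
    if (k0 < 0) k0 = 0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    double c000 = arr[idx3(i0, j0, k0, n1, n2)];
    double c100 = arr[idx3(i0 + 1, j0, k0, n1, n2)];
    double c010 = arr[idx3(i0, j0 + 1, k0, n1, n2)];
    double c110 = arr[idx3(i0 + 1, j0 + 1, k0, n1, n2)];
    double c001 = arr[idx3(i0, j0, k0 + 1, n1, n2)];
    double c101 = arr[idx3(i0 + 1, j0, k0 + 1, n1, n2)];
    double c011 = arr[idx3(i0, j0 + 1, k0 + 1, n1, n2)];
    double c111 = arr[idx3(i0 + 1, j0 + 1, k0 + 1, n1, n2)];
    double c00 = c000 + fx * (c100 - c000);
    double c10 = c010 + fx * (c110 - c010);
    double c01 = c001 + fx * (c101 - c001);
    double c11 = c011 + fx * (c111 - c011);
    double c0 = c00 + fy * (c10 - c00);
    double c1 = c01 + fy * (c11 - c01);
    out[p] = c0 + fz * (c1 - c0);
  }
  return out;
}

// Nearest-neighbour interpolation (for label maps).
// [[Rcpp::export]]
NumericVector sample_nearest_cpp(NumericVector arr, IntegerVector dim,
                                 NumericMatrix vox, double fill) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t m = vox.nrow();
  NumericVector out(m);
  for (R_xlen_t p = 0; p < m; ++p) {
    double x = vox(p, 0), y = vox(p, 1), z = vox(p, 2);
    if (!(x >= -0.5 && x <= n1 - 0.5 && y >= -0.5 && y <= n2 - 0.5 &&
          z >= -0.5 && z <= n3 - 0.5)) {
      out[p] = fill;
      continue;
    }
    int i = (int)std::lround(x), j = (int)std::lround(y),
        k = (int)std::lround(z);
    if (i < 0) i = 0;
    if (i > n1 - 1) i = n1 - 1;
    if (j < 0) j = 0;
    if (j > n2 - 1) j = n2 - 1;
    if (k < 0) k = 0;
    if (k > n3 - 1) k = n3 - 1;
    out[p] = arr[idx3(i, j, k, n1, n2)];
  }
  return out;
}

// Cubic B-spline FFD: evaluate displacement at points given precomputed
// per-axis base control indices (0-based, first of the 4 support nodes)
// and the 4 basis weights per axis. theta is ncp x 3 (column-major over the
// control lattice of dims cdim).
// [[Rcpp::export]]
NumericMatrix ffd_eval_cpp(NumericMatrix theta, IntegerVector cdim,
                           IntegerMatrix base, NumericMatrix wx,
                           NumericMatrix wy, NumericMatrix wz) {
  const int c1 = cdim[0], c2 = cdim[1];
  const R_xlen_t m = base.nrow();
  NumericMatrix out(m, 3);
  for (R_xlen_t p = 0; p < m; ++p) {
    const int bi = base(p, 0), bj = base(p, 1), bk = base(p, 2);
    double sx = 0.0, sy = 0.0, sz = 0.0;
    for (int c = 0; c < 4; ++c) {
      const double wc = wz(p, c);
      if (wc == 0.0) continue;
      for (int b = 0; b < 4; ++b) {
        const double wbc = wy(p, b) * wc;
        if (wbc == 0.0) continue;
        const R_xlen_t off = idx3(bi, bj + b, bk + c, c1, c2);
        for (int a = 0; a < 4; ++a) {
          const double w = wx(p, a) * wbc;
          const R_xlen_t ci = off + a;
          sx += w * theta(ci, 0);
          sy += w * theta(ci, 1);
          sz += w * theta(ci, 2);
        }
      }
    }
    out(p, 0) = sx;
    out(p, 1) = sy;
    out(p, 2) = sz;
  }
  return out;
}

// Adjoint of ffd_eval: scatter per-point 3-vectors back onto the control
// lattice (gradient accumulation).
// [[Rcpp::export]]
NumericMatrix ffd_scatter_cpp(NumericMatrix vals, IntegerVector cdim,
                              IntegerMatrix base, NumericMatrix wx,
                              NumericMatrix wy, NumericMatrix wz) {
  const int c1 = cdim[0], c2 = cdim[1], c3 = cdim[2];
  const R_xlen_t ncp = (R_xlen_t)c1 * c2 * c3;
  const R_xlen_t m = base.nrow();
  NumericMatrix out(ncp, 3);
  for (R_xlen_t p = 0; p < m; ++p) {
    const int bi = base(p, 0), bj = base(p, 1), bk = base(p, 2);
    const double vx = vals(p, 0), vy = vals(p, 1), vz = vals(p, 2);
    for (int c = 0; c < 4; ++c) {
      const double wc = wz(p, c);
      if (wc == 0.0) continue;
      for (int b = 0; b < 4; ++b) {
        const double wbc = wy(p, b) * wc;
        if (wbc == 0.0) continue;
        const R_xlen_t off = idx3(bi, bj + b, bk + c, c1, c2);
        for (int a = 0; a < 4; ++a) {
          const double w = wx(p, a) * wbc;
          const R_xlen_t ci = off + a;
          out(ci, 0) += w * vx;
          out(ci, 1) += w * vy;
          out(ci, 2) += w * vz;
        }
      }
    }
  }
  return out;
}
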