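#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Shared trilinear sampler over a column-major 3D array with voxel-center
// geometry (origin = world position of voxel (0,0,0), index = (p-origin)/spacing).
// Points outside the voxel-center hull are flagged outside (no extrapolation).
// If a validity mask is supplied, a sample touching any invalid corner with
// non-negligible weight is itself invalid.
static inline bool tri_sample(const double* v, const int* dim,
                              const double* origin, const double* spacing,
                              const int* valid, bool has_valid,
                              double px, double py, double pz, double& out) {
  const double eps = 1e-9;
  const double p[3] = {px, py, pz};
  int i0[3];
  double w[3];
  for (int a = 0; a < 3; ++a) {
    double t = (p[a] - origin[a]) / spacing[a];
    if (t < -eps || t > dim[a] - 1 + eps) return false;
    if (t < 0.0) t = 0.0;
    if (t > dim[a] - 1) t = dim[a] - 1;
    if (dim[a] == 1) { i0[a] = 0; w[a] = 0.0; continue; }
    int i = (int)std::floor(t);
    if (i > dim[a] - 2) i = dim[a] - 2;  // upper boundary lands in last cell
    i0[a] = i;
    w[a] = t - i;
  }
  const int s1 = dim[0], s2 = dim[0] * dim[1];
  double acc = 0.0;
  for (int c = 0; c < 8; ++c) {
    const int bx = c & 1, by = (c >> 1) & 1, bz = (c >> 2) & 1;
    const int ix = i0[0] + (dim[0] == 1 ? 0 : bx);
    const int iy = i0[1] + (dim[1] == 1 ? 0 : by);
    const int iz = i0[2] + (dim[2] == 1 ? 0 : bz);
    const double wc = (bx ? w[0] : 1.0 - w[0]) *
                      (by ? w[1] : 1.0 - w[1]) *
                      (bz ? w[2] : 1.0 - w[2]);
    if (wc == 0.0) continue;
    const R_xlen_t idx = (R_xlen_t)ix + (R_xlen_t)s1 * iy + (R_xlen_t)s2 * iz;
    if (has_valid && !valid[idx]) {
      if (wc > 1e-12) return false;
      continue;
    }
    acc += wc * v[idx];
  }
  out = acc;
  return true;
}

// [[Rcpp::export]]
List trilinear_sample_cpp(NumericVector values, IntegerVector dim,
                          NumericVector origin, NumericVector spacing,
                          NumericMatrix pts,
                          LogicalVector valid, bool has_valid) {
  const R_xlen_t n = pts.nrow();
  NumericVector out(n);
  LogicalVector inside(n);
  const double* v = values.begin();
  const int* d = dim.begin();
  const double* o = origin.begin();
  const double* s = spacing.begin();
  const int* vm = has_valid ? valid.begin() : (const int*)nullptr;
  for (R_xlen_t i = 0; i < n; ++i) {
    double val;
    bool ok = tri_sample(v, d, o, s, vm, has_valid,
                         pts(i, 0), pts(i, 1), pts(i, 2), val);
    inside[i] = ok;
    out[i] = ok ? val : NA_REAL;
  }
  return List::create(_["values"] = out, _["inside"] = inside);
}

// Resample a moving grid onto a target lattice through a rigid transform.
// The transform maps moving-grid world coordinates onto target-grid world
// coordinates (content moves forward); each target voxel is therefore filled
// by sampling the moving grid at R^-1 (x - t).
// [[Rcpp::export]]
List resample_grid_cpp(NumericVector values, IntegerVector dim,
                       NumericVector origin, NumericVector spacing,
                       LogicalVector valid, bool has_valid,
                       IntegerVector tdim, NumericVector torigin,
                       NumericVector tspacing,
                       NumericMatrix rot_inv, NumericVector trans) {
  const R_xlen_t n = (R_xlen_t)tdim[0] * tdim[1] * tdim[2];
  NumericVector out(n);
  LogicalVector ovalid(n);
  const double* v = values.begin();
  const int* d = dim.begin();
  const double* o = origin.begin();
  const double* s = spacing.begin();
  const int* vm = has_valid ? valid.begin() : (const int*)nullptr;
  double R[9];
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c) R[3 * r + c] = rot_inv(r, c);
  R_xlen_t q = 0;
  for (int k = 0; k < tdim[2]; ++k) {
    const double wz = torigin[2] + k * tspacing[2];
    for (int j = 0; j < tdim[1]; ++j) {
      const double wy = torigin[1] + j * tspacing[1];
      for (int i = 0; i < tdim[0]; ++i, ++q) {
        const double wx = torigin[0] + i * tspacing[0];
        const double dx = wx - trans[0], dy = wy - trans[1], dz = wz - trans[2];
        const double mx = R[0] * dx + R[1] * dy + R[2] * dz;
        const double my = R[3] * dx + R[4] * dy + R[5] * dz;
        const double mz = R[6] * dx + R[7] * dy + R[8] * dz;
        double val;
        bool ok = tri_sample(v, d, o, s, vm, has_valid, mx, my, mz, val);
        ovalid[q] = ok;
        out[q] = ok ? val : 0.0;
      }
    }
  }
  return List::create(_["values"] = out, _["valid"] = ovalid);
}
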