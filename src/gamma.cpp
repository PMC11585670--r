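#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Local copy of the trilinear sampler (kept in sync with trilinear.cpp; the
// gamma engine needs it in its inner loop and the two files stay independent
// translation units).
static inline bool tri_sample_g(const double* v, const int* dim,
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
    if (i > dim[a] - 2) i = dim[a] - 2;
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

struct Candidate {
  double dx, dy, dz, d2;
};

// Gamma-index engine. For each reference voxel at or above the absolute dose
// threshold, minimises
//   gamma^2 = (|p - r| / dta)^2 + ((D_eval(p) - D_ref(r)) / dd)^2
// over candidate points p on a sub-grid of the given step within the given
// search radius around r, sampling the evaluated grid trilinearly. With
// `prune`, candidates are visited in order of increasing distance and the
// search stops as soon as the distance term alone reaches the current best
// gamma^2 -- a lossless cut since all remaining candidates are farther.
// `local_norm` switches the dose criterion denominator from the single
// global value `dd_abs` to `dd_frac * D_ref(r)` per voxel.
// [[Rcpp::export]]
List gamma_engine_cpp(NumericVector rvalues, IntegerVector rdim,
                      NumericVector rorigin, NumericVector rspacing,
                      LogicalVector rvalid, bool r_has_valid,
                      NumericVector evalues, IntegerVector edim,
                      NumericVector eorigin, NumericVector espacing,
                      LogicalVector evalid, bool e_has_valid,
                      double dd_abs, double dd_frac, bool local_norm,
                      double dta, double thr_abs,
                      double radius, double step, bool prune) {
  // candidate offsets sorted by distance, always including the origin
  std::vector<Candidate> cands;
  const int m = (int)std::floor(radius / step + 1e-9);
  const double r2max = radius * radius + 1e-12;
  for (int k = -m; k <= m; ++k)
    for (int j = -m; j <= m; ++j)
      for (int i = -m; i <= m; ++i) {
        const double dx = i * step, dy = j * step, dz = k * step;
        const double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 <= r2max) cands.push_back({dx, dy, dz, d2});
      }
  std::stable_sort(cands.begin(), cands.end(),
                   [](const Candidate& a, const Candidate& b) { return a.d2 < b.d2; });

  const R_xlen_t n = (R_xlen_t)rdim[0] * rdim[1] * rdim[2];
  NumericVector gamma(n, NA_REAL);
  const double* rv = rvalues.begin();
  const int* rvm = r_has_valid ? rvalid.begin() : (const int*)nullptr;
  const double* ev = evalues.begin();
  const int* ed = edim.begin();
  const double* eo = eorigin.begin();
  const double* es = espacing.begin();
  const int* evm = e_has_valid ? evalid.begin() : (const int*)nullptr;
  const double dta2 = dta * dta;

  R_xlen_t n_eval = 0, n_pass = 0;
  R_xlen_t q = 0;
  for (int k = 0; k < rdim[2]; ++k) {
    const double wz = rorigin[2] + k * rspacing[2];
    for (int j = 0; j < rdim[1]; ++j) {
      const double wy = rorigin[1] + j * rspacing[1];
      for (int i = 0; i < rdim[0]; ++i, ++q) {
        if (r_has_valid && !rvm[q]) continue;
        const double dref = rv[q];
        if (dref < thr_abs) continue;
        const double wx = rorigin[0] + i * rspacing[0];
        const double dd = local_norm ? dd_frac * dref : dd_abs;
        const double dd2 = dd * dd;
        double best = R_PosInf;
        for (const Candidate& c : cands) {
          const double dist_term = c.d2 / dta2;
          if (prune && dist_term >= best) break;
          double de;
          if (!tri_sample_g(ev, ed, eo, es, evm, e_has_valid,
                            wx + c.dx, wy + c.dy, wz + c.dz, de)) continue;
          const double diff = de - dref;
          const double g2 = dist_term + diff * diff / dd2;
          if (g2 < best) best = g2;
        }
        if (R_finite(best)) {
          const double g = std::sqrt(best);
          gamma[q] = g;
          ++n_eval;
          if (g <= 1.0 + 1e-9) ++n_pass;
        }
      }
    }
  }
  return List::create(_["gamma"] = gamma,
                      _["n_evaluated"] = (double)n_eval,
                      _["n_pass"] = (double)n_pass);
}
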