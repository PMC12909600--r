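#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>
#include <algorithm>

using namespace Rcpp;

struct Offset { double dx, dy, dz, r2; };

// Trilinear interpolation of dose at world point (wx,wy,wz); returns false
// when the point lies outside the evaluated grid (no extrapolation).
static bool trilinear(const NumericVector& dose, const int* dims,
                      const double* origin, const double* spacing,
                      double wx, double wy, double wz, double* val) {
  double u[3] = { (wx - origin[0]) / spacing[0],
                  (wy - origin[1]) / spacing[1],
                  (wz - origin[2]) / spacing[2] };
  int i0[3];
  double fr[3];
  for (int a = 0; a < 3; ++a) {
    if (u[a] < 0.0 || u[a] > dims[a] - 1) return false;
    i0[a] = (int)std::floor(u[a]);
    if (i0[a] == dims[a] - 1) --i0[a]; // sample exactly on the far face
    if (i0[a] < 0) i0[a] = 0;
    fr[a] = u[a] - i0[a];
    if (dims[a] == 1) { i0[a] = 0; fr[a] = 0.0; }
  }
  R_xlen_t nx = dims[0], nxy = (R_xlen_t)dims[0] * dims[1];
  double acc = 0.0;
  for (int c = 0; c < 8; ++c) {
    int di = c & 1, dj = (c >> 1) & 1, dk = (c >> 2) & 1;
    int ii = i0[0] + (dims[0] > 1 ? di : 0);
    int jj = i0[1] + (dims[1] > 1 ? dj : 0);
    int kk = i0[2] + (dims[2] > 1 ? dk : 0);
    double w = (di ? fr[0] : 1.0 - fr[0]) *
               (dj ? fr[1] : 1.0 - fr[1]) *
               (dk ? fr[2] : 1.0 - fr[2]);
    acc += w * dose[ii + nx * jj + nxy * kk];
  }
  *val = acc;
  return true;
}

// 3D gamma index, reference-voxel loop with a distance-sorted search pattern
// and early termination once the distance term alone exceeds the running
// minimum. Returns a vector of gamma values (NA below the dose threshold).
// [[Rcpp::export]]
NumericVector gamma_core_cpp(NumericVector ref, IntegerVector rdims,
                             NumericVector rorigin, NumericVector rspacing,
                             NumericVector ev, IntegerVector edims,
                             NumericVector eorigin, NumericVector espacing,
                             double dd_frac, double norm_dose_gy,
                             double dta_mm, double thresh_gy,
                             double search_radius_mm, double step_mm,
                             bool local_norm) {
  const int nx = rdims[0], ny = rdims[1], nz = rdims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n, NA_REAL);

  // search pattern: cubic sub-grid of displacements, sorted by radius
  int m = (int)std::floor(search_radius_mm / step_mm);
  std::vector<Offset> offs;
  offs.reserve((size_t)(2 * m + 1) * (2 * m + 1) * (2 * m + 1));
  for (int a = -m; a <= m; ++a)
    for (int b = -m; b <= m; ++b)
      for (int c = -m; c <= m; ++c) {
        double dx = a * step_mm, dy = b * step_mm, dz = c * step_mm;
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 <= search_radius_mm * search_radius_mm)
          offs.push_back({dx, dy, dz, r2});
      }
  std::sort(offs.begin(), offs.end(),
            [](const Offset& a, const Offset& b) { return a.r2 < b.r2; });

  const double dta2 = dta_mm * dta_mm;
  const int ed[3] = { edims[0], edims[1], edims[2] };
  const double eo[3] = { eorigin[0], eorigin[1], eorigin[2] };
  const double es[3] = { espacing[0], espacing[1], espacing[2] };

  for (int k = 0; k < nz; ++k) {
    double wz = rorigin[2] + k * rspacing[2];
    for (int j = 0; j < ny; ++j) {
      double wy = rorigin[1] + j * rspacing[1];
      for (int i = 0; i < nx; ++i) {
        R_xlen_t idx = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        double dr = ref[idx];
        if (dr < thresh_gy) continue;
        double wx = rorigin[0] + i * rspacing[0];
        double dd = dd_frac * (local_norm ? dr : norm_dose_gy);
        if (dd <= 0.0) continue;
        double best = std::numeric_limits<double>::infinity();
        for (const Offset& o : offs) {
          double dist_term = o.r2 / dta2;
          if (dist_term >= best) break; // sorted: nothing better remains
          double de;
          if (!trilinear(ev, ed, eo, es, wx + o.dx, wy + o.dy, wz + o.dz, &de))
            continue;
          double dterm = (dr - de) / dd;
          double g2 = dist_term + dterm * dterm;
          if (g2 < best) best = g2;
          if (best == 0.0) break;
        }
        if (std::isfinite(best)) out[idx] = std::sqrt(best);
      }
    }
  }
  out.attr("dim") = rdims;
  return out;
}
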