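#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1D lower envelope of parabolas (Felzenszwalb & Huttenlocher) with squared
// grid step s2; f may contain +Inf (no site on that line).
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 double s2, std::vector<int>& v, std::vector<double>& z) {
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    double fq = f[q] + s2 * (double)q * q;
    double s = 0.0;
    while (k >= 0) {
      double fv = f[v[k]] + s2 * (double)v[k] * v[k];
      s = (fq - fv) / (2.0 * s2 * (q - v[k]));
      if (s <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    z[k] = (k == 0) ? -INF : s;
    z[k + 1] = INF;
  }
  if (k < 0) { // no finite site on this line
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (z[j + 1] < q) ++j;
    double dq = (double)q - v[j];
    d[q] = s2 * dq * dq + f[v[j]];
  }
}

// Exact squared Euclidean distance (mm^2) from every voxel center to the
// nearest TRUE voxel center. Voxels of a regular axis-aligned grid with
// per-axis spacing (mm); column-major layout as in R arrays.
// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dims,
                         NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  double s2 = spacing[0] * spacing[0];
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      dt1d(f, d, nx, s2, v, z);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // pass along y
  s2 = spacing[1] * spacing[1];
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)nx * j];
      dt1d(f, d, ny, s2, v, z);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)nx * j] = d[j];
    }
  // pass along z
  s2 = spacing[2] * spacing[2];
  R_xlen_t stride = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      for (int k = 0; k < nz; ++k) f[k] = out[base + stride * k];
      dt1d(f, d, nz, s2, v, z);
      for (int k = 0; k < nz; ++k) out[base + stride * k] = d[k];
    }
  out.attr("dim") = dims;
  return out;
}
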