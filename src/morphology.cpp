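#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform, separable lower-envelope
// algorithm (Felzenszwalb & Huttenlocher 2012), with per-axis spacing so
// anisotropic voxels (pixel size != z step) are handled in physical units.
// "No site" is encoded as a large finite sentinel (> squared grid diameter),
// which the plain envelope algorithm handles without special cases; the R
// wrapper maps values beyond the grid diameter back to Inf.
// ---------------------------------------------------------------------------

// 1D transform: d[q] = min_j ( (s*(q-j))^2 + f[j] )
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double s) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  const double s2 = s * s;
  for (int q = 1; q < n; ++q) {
    double sep = ((f[q] + s2 * (double)q * q) -
                  (f[v[k]] + s2 * (double)v[k] * v[k])) /
                 (2.0 * s2 * (q - v[k]));
    while (sep <= z[k]) {
      --k;
      sep = ((f[q] + s2 * (double)q * q) -
             (f[v[k]] + s2 * (double)v[k] * v[k])) /
            (2.0 * s2 * (q - v[k]));
    }
    ++k;
    v[k] = q;
    z[k] = sep;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = s * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// mask: logical array (column-major) of dims d1 x d2 x d3 (d3 may be 1);
// returns squared physical distance from each voxel to the nearest TRUE
// voxel (Inf when the mask is empty).
// [[Rcpp::export]]
NumericVector cpp_sqedt(LogicalVector mask, IntegerVector dim,
                        NumericVector spacing) {
  int d1 = dim[0], d2 = dim[1], d3 = (dim.size() > 2 ? dim[2] : 1);
  double s1 = spacing[0], s2 = spacing[1],
         s3 = (spacing.size() > 2 ? spacing[2] : 1.0);
  R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  double diam = s1 * d1 + s2 * d2 + s3 * d3;
  double big = 4.0 * diam * diam + 1.0;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? 0.0 : big;

  int nmax = std::max(d1, std::max(d2, d3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along dim 1 (stride 1)
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j) {
      R_xlen_t off = (R_xlen_t)k * d1 * d2 + (R_xlen_t)j * d1;
      for (int i = 0; i < d1; ++i) f[i] = g[off + i];
      dt1d(f, d, v, z, d1, s1);
      for (int i = 0; i < d1; ++i) g[off + i] = d[i];
    }
  // pass along dim 2 (stride d1)
  for (int k = 0; k < d3; ++k)
    for (int i = 0; i < d1; ++i) {
      R_xlen_t off = (R_xlen_t)k * d1 * d2 + i;
      for (int j = 0; j < d2; ++j) f[j] = g[off + (R_xlen_t)j * d1];
      dt1d(f, d, v, z, d2, s2);
      for (int j = 0; j < d2; ++j) g[off + (R_xlen_t)j * d1] = d[j];
    }
  // pass along dim 3 (stride d1*d2)
  if (d3 > 1) {
    R_xlen_t pl = (R_xlen_t)d1 * d2;
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        R_xlen_t off = (R_xlen_t)j * d1 + i;
        for (int k = 0; k < d3; ++k) f[k] = g[off + (R_xlen_t)k * pl];
        dt1d(f, d, v, z, d3, s3);
        for (int k = 0; k < d3; ++k) g[off + (R_xlen_t)k * pl] = d[k];
      }
  }
  double cut = diam * diam; // any true distance is below this
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (g[i] > cut) ? R_PosInf : g[i];
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labeling (iterative DFS). 2D: connectivity 4 or 8.
// 3D: face connectivity (6). Labels are assigned in column-major scan order
// of each component's first-visited pixel, starting at 1; 0 = background.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label2d(LogicalVector mask, IntegerVector dim,
                          int connectivity) {
  int ny = dim[0], nx = dim[1];
  R_xlen_t n = (R_xlen_t)ny * nx;
  IntegerVector lab(n, 0);
  static const int dy8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  static const int dx8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nn = (connectivity == 8) ? 8 : 4;
  int cur = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    lab[s] = cur;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int y = (int)(p % ny), x = (int)(p / ny);
      for (int t = 0; t < nn; ++t) {
        int yy = y + dy8[t], xx = x + dx8[t];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        R_xlen_t q = (R_xlen_t)xx * ny + yy;
        if (mask[q] && lab[q] == 0) {
          lab[q] = cur;
          stack.push_back(q);
        }
      }
    }
  }
  return lab;
}

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim) {
  int d1 = dim[0], d2 = dim[1], d3 = (dim.size() > 2 ? dim[2] : 1);
  R_xlen_t pl = (R_xlen_t)d1 * d2, n = pl * d3;
  IntegerVector lab(n, 0);
  int cur = 0;
  std::vector<R_xlen_t> stack;
  const int di[6] = {-1, 1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, -1, 1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, -1, 1};
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    lab[s] = cur;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int k = (int)(p / pl);
      int rem = (int)(p % pl);
      int j = rem / d1, i = rem % d1;
      for (int t = 0; t < 6; ++t) {
        int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
        if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3)
          continue;
        R_xlen_t q = (R_xlen_t)kk * pl + (R_xlen_t)jj * d1 + ii;
        if (mask[q] && lab[q] == 0) {
          lab[q] = cur;
          stack.push_back(q);
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Voxel surface area: sum of exposed face areas. A face between an inside
// voxel and an outside voxel (or the array boundary) contributes the product
// of the two spacings orthogonal to its axis.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_voxel_surface(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  int d1 = dim[0], d2 = dim[1], d3 = (dim.size() > 2 ? dim[2] : 1);
  double s1 = spacing[0], s2 = spacing[1],
         s3 = (spacing.size() > 2 ? spacing[2] : 1.0);
  double a1 = s2 * s3, a2 = s1 * s3, a3 = s1 * s2;
  R_xlen_t pl = (R_xlen_t)d1 * d2;
  double area = 0.0;
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        R_xlen_t p = (R_xlen_t)k * pl + (R_xlen_t)j * d1 + i;
        if (!mask[p]) continue;
        if (i == 0 || !mask[p - 1]) area += a1;
        if (i == d1 - 1 || !mask[p + 1]) area += a1;
        if (j == 0 || !mask[p - d1]) area += a2;
        if (j == d2 - 1 || !mask[p + d1]) area += a2;
        if (k == 0 || !mask[p - pl]) area += a3;
        if (k == d3 - 1 || !mask[p + pl]) area += a3;
      }
  return area;
}
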