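#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Arrays are R 3-D arrays with dim = c(ny, nx, nz); linear index
// i = iy + ny * (ix + nx * iz), 0-based here.

// 26-connected component labelling by iterative flood fill.
// Returns integer labels (0 = background), labelled in raster order.
// [[Rcpp::export]]
IntegerVector cc_label_26(LogicalVector mask, IntegerVector dim) {
  const int ny = dim[0], nx = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  stack.reserve(1024);
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int iy = (int)(cur % ny);
      int ix = (int)((cur / ny) % nx);
      int iz = (int)(cur / ((R_xlen_t)ny * nx));
      for (int dz = -1; dz <= 1; ++dz) {
        int jz = iz + dz;
        if (jz < 0 || jz >= nz) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          int jx = ix + dx;
          if (jx < 0 || jx >= nx) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            if (dy == 0 && dx == 0 && dz == 0) continue;
            int jy = iy + dy;
            if (jy < 0 || jy >= ny) continue;
            R_xlen_t j = jy + (R_xlen_t)ny * (jx + (R_xlen_t)nx * jz);
            if (mask[j] && lab[j] == 0) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

static std::vector<double> gauss_kernel(double sigma) {
  int r = (int)std::ceil(3.0 * sigma);
  if (r < 1) r = 1;
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    double v = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    k[i + r] = v;
    s += v;
  }
  for (auto &v : k) v /= s;
  return k;
}

static inline int reflect_idx(int i, int n) {
  // reflect-at-edge boundary (a b c | c b a)
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Separable Gaussian blur; sigma_vox gives the sigma in voxel units per
// axis in dim order (y, x, z); an axis with sigma <= 0 is skipped.
// [[Rcpp::export]]
NumericVector gauss_blur_3d(NumericVector img, IntegerVector dim,
                            NumericVector sigma_vox) {
  const int ny = dim[0], nx = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  std::vector<double> a(img.begin(), img.end());
  std::vector<double> b(n);
  const int strides[3] = {1, ny, ny * nx};
  const int sizes[3] = {ny, nx, nz};
  for (int ax = 0; ax < 3; ++ax) {
    double sg = sigma_vox[ax];
    if (sg <= 0) continue;
    std::vector<double> k = gauss_kernel(sg);
    int r = ((int)k.size() - 1) / 2;
    int len = sizes[ax];
    R_xlen_t stride = strides[ax];
    // iterate over all lines along axis ax
    int o1 = (ax == 0) ? nx : ny;          // sizes of the two other axes
    int o2 = (ax == 2) ? nx : nz;
    R_xlen_t s1 = (ax == 0) ? strides[1] : strides[0];
    R_xlen_t s2 = (ax == 2) ? strides[1] : strides[2];
    for (int i2 = 0; i2 < o2; ++i2) {
      for (int i1 = 0; i1 < o1; ++i1) {
        R_xlen_t base = i1 * s1 + i2 * s2;
        for (int p = 0; p < len; ++p) {
          double acc = 0.0;
          for (int q = -r; q <= r; ++q) {
            int pp = reflect_idx(p + q, len);
            acc += k[q + r] * a[base + (R_xlen_t)pp * stride];
          }
          b[base + (R_xlen_t)p * stride] = acc;
        }
      }
    }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// 1-D squared distance transform (Felzenszwalb & Huttenlocher) on a
// grid with sample spacing w.
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, int n, double w) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;  // only finite parabolas enter the envelope
    double xq = q * w;
    double s = 0.0;
    while (k >= 0) {
      double xv = v[k] * w;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) --k; else break;
    }
    if (k < 0) {
      k = 0;
      v[0] = q;
      z[0] = -INF;
    } else {
      ++k;
      v[k] = q;
      z[k] = s;
    }
    z[k + 1] = INF;
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * w;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * w;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// Squared Euclidean distance (physical units) from every voxel center to
// the nearest true voxel center of `mask`; spacing in dim order (y, x, z).
// All-false mask -> Inf everywhere.
// [[Rcpp::export]]
NumericVector edt_sq_3d(LogicalVector mask, IntegerVector dim,
                        NumericVector spacing) {
  const int ny = dim[0], nx = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> a(n);
  for (R_xlen_t i = 0; i < n; ++i) a[i] = mask[i] ? 0.0 : INF;
  const int strides[3] = {1, ny, ny * nx};
  const int sizes[3] = {ny, nx, nz};
  int maxlen = std::max(ny, std::max(nx, nz));
  std::vector<double> f(maxlen), d(maxlen), z(maxlen + 1);
  std::vector<int> v(maxlen);
  for (int ax = 0; ax < 3; ++ax) {
    int len = sizes[ax];
    R_xlen_t stride = strides[ax];
    double w = spacing[ax];
    int o1 = (ax == 0) ? nx : ny;
    int o2 = (ax == 2) ? nx : nz;
    R_xlen_t s1 = (ax == 0) ? strides[1] : strides[0];
    R_xlen_t s2 = (ax == 2) ? strides[1] : strides[2];
    for (int i2 = 0; i2 < o2; ++i2) {
      for (int i1 = 0; i1 < o1; ++i1) {
        R_xlen_t base = i1 * s1 + i2 * s2;
        bool any = false;
        for (int p = 0; p < len; ++p) {
          f[p] = a[base + (R_xlen_t)p * stride];
          if (f[p] < INF) any = true;
        }
        if (!any) continue;
        dt1d(f, d, v, z, len, w);
        for (int p = 0; p < len; ++p) a[base + (R_xlen_t)p * stride] = d[p];
      }
    }
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// Distance from each point (rows of pts, physical y/x/z coords) to the
// nearest vertex of a polyline set given as a single matrix of vertices.
// Brute force; used for rod placement against filament axes.
// [[Rcpp::export]]
NumericVector min_dist_to_points(NumericMatrix pts, NumericMatrix ref) {
  int n = pts.nrow(), m = ref.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = std::numeric_limits<double>::infinity();
    for (int j = 0; j < m; ++j) {
      double dy = pts(i, 0) - ref(j, 0);
      double dx = pts(i, 1) - ref(j, 1);
      double dz = pts(i, 2) - ref(j, 2);
      double d2 = dy * dy + dx * dx + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
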