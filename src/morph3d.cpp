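#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Volumetric primitives shared by the segmentation, spot-detection and
// granulometry code. Arrays are R arrays with dim = c(nz, ny, nx); the
// linear index of voxel (z, y, x) is z + nz * (y + ny * x) (0-based here).
// spacing = (dz, dy, dx) in micrometres.

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared distance transform (Felzenszwalb & Huttenlocher lower
// envelope) along a line whose sample positions are i * s.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double s) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF && f[v[k]] == INF) { // both parabolas at +inf: skip
      continue;
    }
    double xq = q * s, xv = v[k] * s;
    double sden = 2.0 * (xq - xv);
    double sp = (f[q] + xq * xq - (f[v[k]] + xv * xv)) / sden;
    while (k > 0 && sp <= z[k]) {
      --k;
      xv = v[k] * s;
      sden = 2.0 * (xq - xv);
      sp = (f[q] + xq * xq - (f[v[k]] + xv * xv)) / sden;
    }
    if (f[v[k]] == INF) { // envelope so far is +inf: replace it
      v[k] = q;
    } else {
      ++k;
      v[k] = q;
      z[k] = sp;
      z[k + 1] = INF;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * s;
    d[q] = (f[v[k]] == INF) ? INF : (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// Squared Euclidean distance (physical units) from every voxel to the
// nearest voxel centre where fg == 0. Voxels with fg == 0 get 0.
// [[Rcpp::export]]
NumericVector cpp_sqedt(IntegerVector fg, IntegerVector dim,
                        NumericVector spacing) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = fg[i] ? INF : 0.0;

  // pass along z (stride 1)
  {
    std::vector<double> f(nz), out(nz);
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
        bool any = false;
        for (int z = 0; z < nz; ++z) { f[z] = d[base + z]; if (f[z] < INF) any = true; }
        if (!any) continue;
        dt1d(f, out, nz, spacing[0]);
        for (int z = 0; z < nz; ++z) d[base + z] = out[z];
      }
  }
  // pass along y (stride nz)
  {
    std::vector<double> f(ny), out(ny);
    for (int x = 0; x < nx; ++x)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t base = z + (R_xlen_t)nz * ny * x;
        bool any = false;
        for (int y = 0; y < ny; ++y) { f[y] = d[base + (R_xlen_t)nz * y]; if (f[y] < INF) any = true; }
        if (!any) continue;
        dt1d(f, out, ny, spacing[1]);
        for (int y = 0; y < ny; ++y) d[base + (R_xlen_t)nz * y] = out[y];
      }
  }
  // pass along x (stride nz*ny)
  {
    std::vector<double> f(nx), out(nx);
    R_xlen_t sx = (R_xlen_t)nz * ny;
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t base = z + (R_xlen_t)nz * y;
        bool any = false;
        for (int x = 0; x < nx; ++x) { f[x] = d[base + sx * x]; if (f[x] < INF) any = true; }
        if (!any) continue;
        dt1d(f, out, nx, spacing[2]);
        for (int x = 0; x < nx; ++x) d[base + sx * x] = out[x];
      }
  }
  for (R_xlen_t i = 0; i < n; ++i) if (d[i] == INF) d[i] = R_PosInf;
  return d;
}

// Separable Gaussian blur, reflecting boundary. sigma in voxel units per
// axis; sigma <= 0 skips that axis.
// [[Rcpp::export]]
NumericVector cpp_gauss_blur3d(NumericVector arr, IntegerVector dim,
                               NumericVector sigma_vox) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector cur = clone(arr);
  int dims[3] = {nz, ny, nx};
  R_xlen_t strides[3] = {1, (R_xlen_t)nz, (R_xlen_t)nz * ny};

  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma_vox[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> k(2 * r + 1);
    double ksum = 0;
    for (int i = -r; i <= r; ++i) {
      k[i + r] = std::exp(-0.5 * i * i / (s * s));
      ksum += k[i + r];
    }
    for (size_t i = 0; i < k.size(); ++i) k[i] /= ksum;

    NumericVector nxt(n);
    int len = dims[ax];
    R_xlen_t st = strides[ax];
    int d1 = dims[(ax + 1) % 3], d2 = dims[(ax + 2) % 3];
    R_xlen_t s1 = strides[(ax + 1) % 3], s2 = strides[(ax + 2) % 3];
    std::vector<double> line(len);
    for (int b = 0; b < d2; ++b)
      for (int a = 0; a < d1; ++a) {
        R_xlen_t base = a * s1 + b * s2;
        for (int i = 0; i < len; ++i) line[i] = cur[base + st * i];
        for (int i = 0; i < len; ++i) {
          double acc = 0;
          for (int j = -r; j <= r; ++j) {
            int idx = i + j;
            if (idx < 0) idx = -idx - 1;          // reflect
            if (idx >= len) idx = 2 * len - idx - 1;
            if (idx < 0) idx = 0;                 // guard tiny axes
            if (idx >= len) idx = len - 1;
            acc += k[j + r] * line[idx];
          }
          nxt[base + st * i] = acc;
        }
      }
    cur = nxt;
  }
  return cur;
}

// 26-connected component labeling of a binary mask. Returns integer
// labels 1..k in scan order of component discovery (deterministic).
// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int z = (int)(cur % nz);
      int y = (int)((cur / nz) % ny);
      int x = (int)(cur / ((R_xlen_t)nz * ny));
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            if (!dx && !dy && !dz) continue;
            int zz = z + dz, yy = y + dy, xx = x + dx;
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
              continue;
            R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
            if (mask[j] && !lab[j]) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
    }
  }
  lab.attr("n_labels") = next;
  return lab;
}

// Assign every mask voxel the 1-based index of its nearest seed
// (physical Euclidean distance; ties -> lowest seed index).
// seeds: k x 3 matrix of 0-based (z, y, x) voxel coordinates.
// [[Rcpp::export]]
IntegerVector cpp_nearest_seed(IntegerVector mask, IntegerVector dim,
                               NumericVector spacing, IntegerMatrix seeds) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  int k = seeds.nrow();
  IntegerVector lab(n, 0);
  double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    int z = (int)(i % nz);
    int y = (int)((i / nz) % ny);
    int x = (int)(i / ((R_xlen_t)nz * ny));
    double best = INF;
    int bi = 0;
    for (int s = 0; s < k; ++s) {
      double az = (z - seeds(s, 0)) * dz;
      double ay = (y - seeds(s, 1)) * dy;
      double ax = (x - seeds(s, 2)) * dx;
      double d2 = az * az + ay * ay + ax * ax;
      if (d2 < best - 1e-12) {
        best = d2;
        bi = s + 1;
      }
    }
    lab[i] = bi;
  }
  return lab;
}

// Local maxima of arr above `threshold` within an anisotropic box window
// of half-widths radius_vox = (rz, ry, rx). Plateaus are broken by
// keeping only the lowest linear index among equal-valued neighbours.
// Returns 1-based linear indices.
// [[Rcpp::export]]
IntegerVector cpp_local_maxima(NumericVector arr, IntegerVector dim,
                               IntegerVector radius_vox, double threshold) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int rz = radius_vox[0], ry = radius_vox[1], rx = radius_vox[2];
  std::vector<int> out;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
        double v = arr[i];
        if (!(v > threshold)) continue;
        bool ismax = true;
        for (int xx = std::max(0, x - rx); ismax && xx <= std::min(nx - 1, x + rx); ++xx)
          for (int yy = std::max(0, y - ry); ismax && yy <= std::min(ny - 1, y + ry); ++yy)
            for (int zz = std::max(0, z - rz); zz <= std::min(nz - 1, z + rz); ++zz) {
              R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
              if (j == i) continue;
              if (arr[j] > v || (arr[j] == v && j < i)) {
                ismax = false;
                break;
              }
            }
        if (ismax) out.push_back((int)(i + 1));
      }
  return wrap(out);
}
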