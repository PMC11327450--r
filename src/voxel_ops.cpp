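#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Linear index helpers for a column-major (d1, d2, d3) array.
// R arrays store the first dimension fastest.

// Multi-source breadth-first search over the 6-neighborhood.
// Returns, for every voxel, the L1 (city-block) grid distance to the nearest
// TRUE voxel of `mask`, capped at `cap` (voxels farther than cap get cap + 1).
// On an unobstructed grid, BFS distance over the 6-neighborhood equals the
// Manhattan distance, so {d <= k} is exactly k iterations of binary dilation
// with the connectivity-1 structuring element.
// [[Rcpp::export]]
IntegerVector cpp_l1_distance(LogicalVector mask, IntegerVector dim, int cap) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  if (mask.size() != n) stop("mask length does not match dim");
  IntegerVector dist(n, NA_INTEGER);
  std::vector<int> queue;
  queue.reserve(n / 4 + 1);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i]) {
      dist[i] = 0;
      queue.push_back((int)i);
    }
  }
  const int far = cap + 1;
  size_t head = 0;
  while (head < queue.size()) {
    const int i = queue[head++];
    const int d = dist[i];
    if (d >= cap) continue;
    const int z = i / (d1 * d2);
    const int rem = i - z * d1 * d2;
    const int y = rem / d1;
    const int x = rem - y * d1;
    const int nb[6] = {
      x > 0      ? i - 1       : -1,
      x < d1 - 1 ? i + 1       : -1,
      y > 0      ? i - d1      : -1,
      y < d2 - 1 ? i + d1      : -1,
      z > 0      ? i - d1 * d2 : -1,
      z < d3 - 1 ? i + d1 * d2 : -1};
    for (int k = 0; k < 6; ++k) {
      const int j = nb[k];
      if (j >= 0 && dist[j] == NA_INTEGER) {
        dist[j] = d + 1;
        queue.push_back(j);
      }
    }
  }
  for (R_xlen_t i = 0; i < n; ++i)
    if (dist[i] == NA_INTEGER) dist[i] = far;
  return dist;
}

// Connected-component labeling of a binary volume.
// connectivity 1 -> 6-neighborhood (faces); connectivity 3 -> 26-neighborhood.
// Labels are assigned in raster-scan order of each component's first voxel.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  if (mask.size() != n) stop("mask length does not match dim");
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  // neighbor offsets
  std::vector<int> off_dx, off_dy, off_dz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (s == 0) continue;
        if (connectivity == 1 && s > 1) continue;
        off_dx.push_back(dx); off_dy.push_back(dy); off_dz.push_back(dz);
      }
  const int nn = (int)off_dx.size();
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back((int)s);
    while (!stack.empty()) {
      const int i = stack.back();
      stack.pop_back();
      const int z = i / (d1 * d2);
      const int rem = i - z * d1 * d2;
      const int y = rem / d1;
      const int x = rem - y * d1;
      for (int k = 0; k < nn; ++k) {
        const int xx = x + off_dx[k], yy = y + off_dy[k], zz = z + off_dz[k];
        if (xx < 0 || xx >= d1 || yy < 0 || yy >= d2 || zz < 0 || zz >= d3)
          continue;
        const int j = xx + d1 * (yy + (R_xlen_t)d2 * zz);
        if (mask[j] && lab[j] == 0) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  return lab;
}

// Separable 3D Gaussian blur with reflected boundaries.
// [[Rcpp::export]]
NumericVector cpp_blur3d(NumericVector img, IntegerVector dim, double sigma) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  if (img.size() != n) stop("img length does not match dim");
  if (sigma <= 0) return clone(img);
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> kern(2 * r + 1);
  double ksum = 0.0;
  for (int k = -r; k <= r; ++k) {
    kern[k + r] = std::exp(-0.5 * k * k / (sigma * sigma));
    ksum += kern[k + r];
  }
  for (double &k : kern) k /= ksum;

  std::vector<double> a(img.begin(), img.end()), b(n);
  const int dims[3] = {d1, d2, d3};
  const R_xlen_t strides[3] = {1, d1, (R_xlen_t)d1 * d2};
  for (int ax = 0; ax < 3; ++ax) {
    const int len = dims[ax];
    if (len < 2) continue;  // nothing to blur along a singleton axis
    const R_xlen_t stride = strides[ax];
    for (R_xlen_t i = 0; i < n; ++i) {
      // coordinates of voxel i along axis ax
      R_xlen_t pos = (i / stride) % len;
      double acc = 0.0;
      for (int k = -r; k <= r; ++k) {
        R_xlen_t p = (R_xlen_t)pos + k;
        while (p < 0 || p >= len) {              // reflect at both ends
          if (p < 0) p = -p;
          if (p >= len) p = 2 * (len - 1) - p;
        }
        acc += kern[k + r] * a[i + (p - pos) * stride];
      }
      b[i] = acc;
    }
    std::swap(a, b);
  }
  return NumericVector(a.begin(), a.end());
}
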