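#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Voxel-grid operations on 3D arrays stored R-style (column-major) with
// dimensions (nz, ny, nx): linear index = z + nz * (y + ny * x).

// Separable Gaussian blur, sigma given in voxels per axis (z, y, x).
// Reflecting boundary; kernels renormalised so flat fields are preserved.
// [[Rcpp::export]]
NumericVector cpp_gauss_blur3(NumericVector arr, IntegerVector dim,
                              NumericVector sigma_vox) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<double> cur(arr.begin(), arr.end()), nxt(n);

  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma_vox[axis];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> k(2 * r + 1);
    double sum = 0.0;
    for (int i = -r; i <= r; ++i) {
      k[i + r] = std::exp(-0.5 * i * i / (s * s));
      sum += k[i + r];
    }
    for (int i = 0; i <= 2 * r; ++i) k[i] /= sum;

    int len = (axis == 0) ? nz : (axis == 1) ? ny : nx;
    R_xlen_t stride = (axis == 0) ? 1 : (axis == 1) ? (R_xlen_t)nz
                                                    : (R_xlen_t)nz * ny;
    R_xlen_t nlines = n / len;
    for (R_xlen_t line = 0; line < nlines; ++line) {
      // base index of this line
      R_xlen_t base;
      if (axis == 0) {
        base = line * nz;
      } else if (axis == 1) {
        R_xlen_t zi = line % nz, xi = line / nz;
        base = zi + (R_xlen_t)nz * ny * xi;
      } else {
        base = line; // (z, y) pairs are contiguous
      }
      for (int i = 0; i < len; ++i) {
        double acc = 0.0;
        for (int j = -r; j <= r; ++j) {
          int idx = i + j;
          if (idx < 0) idx = -idx - 1;            // reflect
          if (idx >= len) idx = 2 * len - idx - 1;
          if (idx < 0) idx = 0;
          if (idx >= len) idx = len - 1;
          acc += k[j + r] * cur[base + (R_xlen_t)idx * stride];
        }
        nxt[base + (R_xlen_t)i * stride] = acc;
      }
    }
    cur.swap(nxt);
  }
  NumericVector out(n);
  std::copy(cur.begin(), cur.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}

// Connected-component labelling of a binary 3D mask. connectivity must be
// 6 or 26; with nz == 1 these reduce to 4- and 8-connectivity in 2D.
// Returns integer labels 1..k, 0 for background.
// [[Rcpp::export]]
IntegerVector cpp_label3(LogicalVector mask, IntegerVector dim,
                         int connectivity) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);

  // neighbour offsets
  std::vector<int> oz, oy, ox;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && m != 1) continue;
        oz.push_back(dz); oy.push_back(dy); ox.push_back(dx);
      }
  int nn = (int)oz.size();

  int next_label = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || lab[start] != 0) continue;
    ++next_label;
    lab[start] = next_label;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int z = (int)(v % nz);
      int y = (int)((v / nz) % ny);
      int x = (int)(v / ((R_xlen_t)nz * ny));
      for (int q = 0; q < nn; ++q) {
        int z2 = z + oz[q], y2 = y + oy[q], x2 = x + ox[q];
        if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
          continue;
        R_xlen_t w = z2 + (R_xlen_t)nz * (y2 + (R_xlen_t)ny * x2);
        if (mask[w] && lab[w] == 0) {
          lab[w] = next_label;
          stack.push_back(w);
        }
      }
    }
  }
  lab.attr("dim") = dim;
  lab.attr("n_labels") = next_label;
  return lab;
}
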