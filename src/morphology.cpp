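#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labelling and binary morphology on voxel grids.
// Kept in C++ because volumes run to millions of voxels and the shell of a
// thresholded phantom alone has tens of thousands of surface voxels.

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  IntegerVector lab(n, 0);

  // neighbour offsets
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh > 1) continue;
        offs.push_back({dx, dy, dz});
      }

  int next = 0;
  std::vector<int> stack;
  for (int s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int ci = cur % nx, cj = (cur / nx) % ny, ck = cur / (nx * ny);
      for (const auto &o : offs) {
        int i = ci + o[0], j = cj + o[1], k = ck + o[2];
        if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) continue;
        int t = idx3(i, j, k, nx, ny);
        if (mask[t] && lab[t] == 0) {
          lab[t] = next;
          stack.push_back(t);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Dilation by an arbitrary symmetric structuring element given as voxel
// offsets (m x 3, including or excluding the centre). Outside the grid is
// treated as background.
// [[Rcpp::export]]
LogicalVector binary_dilate_cpp(LogicalVector mask, IntegerVector dims,
                                IntegerMatrix offs) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  LogicalVector out(n, false);
  for (int s = 0; s < n; ++s) {
    if (!mask[s]) continue;
    int ci = s % nx, cj = (s / nx) % ny, ck = s / (nx * ny);
    for (int m = 0; m < offs.nrow(); ++m) {
      int i = ci + offs(m, 0), j = cj + offs(m, 1), k = ck + offs(m, 2);
      if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) continue;
      out[idx3(i, j, k, nx, ny)] = true;
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Erosion: a voxel survives iff every offset lands inside the grid on a
// foreground voxel (outside counts as background).
// [[Rcpp::export]]
LogicalVector binary_erode_cpp(LogicalVector mask, IntegerVector dims,
                               IntegerMatrix offs) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  LogicalVector out(n, false);
  for (int s = 0; s < n; ++s) {
    if (!mask[s]) continue;
    int ci = s % nx, cj = (s / nx) % ny, ck = s / (nx * ny);
    bool keep = true;
    for (int m = 0; m < offs.nrow(); ++m) {
      int i = ci + offs(m, 0), j = cj + offs(m, 1), k = ck + offs(m, 2);
      if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) {
        keep = false;
        break;
      }
      if (!mask[idx3(i, j, k, nx, ny)]) {
        keep = false;
        break;
      }
    }
    if (keep) out[s] = true;
  }
  out.attr("dim") = dims;
  return out;
}
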