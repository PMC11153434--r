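#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Chebyshev (26-neighbourhood) dilation of radius r, separable as a
// running maximum along each axis.
// [[Rcpp::export]]
LogicalVector cpp_dilate_cheb(LogicalVector mask, IntegerVector dims, int r) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<char> a(n), b(n);
  for (int i = 0; i < n; ++i) a[i] = mask[i] ? 1 : 0;
  if (r <= 0) {
    LogicalVector out(n);
    for (int i = 0; i < n; ++i) out[i] = a[i] != 0;
    return out;
  }
  // pass along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      const int base = (z * ny + y) * nx;
      for (int x = 0; x < nx; ++x) {
        char v = 0;
        const int lo = std::max(0, x - r), hi = std::min(nx - 1, x + r);
        for (int t = lo; t <= hi && !v; ++t) v = a[base + t];
        b[base + x] = v;
      }
    }
  // pass along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) {
        char v = 0;
        const int lo = std::max(0, y - r), hi = std::min(ny - 1, y + r);
        for (int t = lo; t <= hi && !v; ++t) v = b[(z * ny + t) * nx + x];
        a[(z * ny + y) * nx + x] = v;
      }
    }
  // pass along z
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) {
        char v = 0;
        const int lo = std::max(0, z - r), hi = std::min(nz - 1, z + r);
        for (int t = lo; t <= hi && !v; ++t) v = a[(t * ny + y) * nx + x];
        b[(z * ny + y) * nx + x] = v;
      }
    }
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = b[i] != 0;
  return out;
}

// 26-connected component labelling by iterative flood fill.
// Returns integer labels (0 = background), labelled in scan order.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      const int v = stack.back();
      stack.pop_back();
      const int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            const int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
              continue;
            const int u = (zz * ny + yy) * nx + xx;
            if (mask[u] && !lab[u]) {
              lab[u] = next;
              stack.push_back(u);
            }
          }
    }
  }
  return lab;
}
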