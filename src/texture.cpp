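#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// The 13 unique direction offsets of the 26-neighbourhood (positive
// lexicographic half); distance 1.
static const int DIRS[13][3] = {
    {1, 0, 0},  {0, 1, 0},  {0, 0, 1},  {1, 1, 0},   {1, -1, 0},
    {1, 0, 1},  {1, 0, -1}, {0, 1, 1},  {0, 1, -1},  {1, 1, 1},
    {1, 1, -1}, {1, -1, 1}, {1, -1, -1}};

static inline bool inside(int x, int y, int z, int nx, int ny, int nz) {
  return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
}

// Gray level co-occurrence counts, one-way, per direction.
// labels: 1..ng inside ROI, 0 outside. Returns ng x ng x 13 array.
// [[Rcpp::export]]
NumericVector cpp_glcm(IntegerVector labels, IntegerVector dims, int ng) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(ng * ng * 13);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int li = labels[(z * ny + y) * nx + x];
        if (!li) continue;
        for (int d = 0; d < 13; ++d) {
          const int xx = x + DIRS[d][0], yy = y + DIRS[d][1],
                    zz = z + DIRS[d][2];
          if (!inside(xx, yy, zz, nx, ny, nz)) continue;
          const int lj = labels[(zz * ny + yy) * nx + xx];
          if (!lj) continue;
          out[(d * ng + (lj - 1)) * ng + (li - 1)] += 1.0;
        }
      }
  out.attr("dim") = IntegerVector::create(ng, ng, 13);
  return out;
}

// Gray level run length counts per direction: ng x maxlen x 13.
// Runs are maximal same-level sequences along a direction; masked-out
// voxels break runs.
// [[Rcpp::export]]
NumericVector cpp_glrlm(IntegerVector labels, IntegerVector dims, int ng) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int maxlen = std::max(nx, std::max(ny, nz));
  NumericVector out(ng * maxlen * 13);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int li = labels[(z * ny + y) * nx + x];
        if (!li) continue;
        for (int d = 0; d < 13; ++d) {
          // run start: predecessor along -d is absent or different
          const int px = x - DIRS[d][0], py = y - DIRS[d][1],
                    pz = z - DIRS[d][2];
          if (inside(px, py, pz, nx, ny, nz) &&
              labels[(pz * ny + py) * nx + px] == li)
            continue;
          int len = 1;
          int cx = x + DIRS[d][0], cy = y + DIRS[d][1], cz = z + DIRS[d][2];
          while (inside(cx, cy, cz, nx, ny, nz) &&
                 labels[(cz * ny + cy) * nx + cx] == li) {
            ++len;
            cx += DIRS[d][0];
            cy += DIRS[d][1];
            cz += DIRS[d][2];
          }
          out[(d * maxlen + (len - 1)) * ng + (li - 1)] += 1.0;
        }
      }
  out.attr("dim") = IntegerVector::create(ng, maxlen, 13);
  return out;
}

// Size zones: 26-connected components of equal gray level.
// Returns a 2-column matrix (level, size), one row per zone.
// [[Rcpp::export]]
IntegerMatrix cpp_glszm_zones(IntegerVector labels, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> stack, lev, siz;
  for (int i = 0; i < n; ++i) {
    if (!labels[i] || seen[i]) continue;
    const int li = labels[i];
    int size = 0;
    seen[i] = 1;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      const int v = stack.back();
      stack.pop_back();
      ++size;
      const int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            const int xx = x + dx, yy = y + dy, zz = z + dz;
            if (!inside(xx, yy, zz, nx, ny, nz)) continue;
            const int u = (zz * ny + yy) * nx + xx;
            if (!seen[u] && labels[u] == li) {
              seen[u] = 1;
              stack.push_back(u);
            }
          }
    }
    lev.push_back(li);
    siz.push_back(size);
  }
  IntegerMatrix out(lev.size(), 2);
  for (size_t r = 0; r < lev.size(); ++r) {
    out(r, 0) = lev[r];
    out(r, 1) = siz[r];
  }
  return out;
}

// Dependence counts: for each ROI voxel with level i, the dependence is
// 1 + number of 26-neighbours inside the ROI with |level - i| <= alpha.
// Returns ng x 27 counts.
// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector labels, IntegerVector dims, int ng,
                       int alpha) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix out(ng, 27);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int li = labels[(z * ny + y) * nx + x];
        if (!li) continue;
        int dep = 1;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              const int xx = x + dx, yy = y + dy, zz = z + dz;
              if (!inside(xx, yy, zz, nx, ny, nz)) continue;
              const int lj = labels[(zz * ny + yy) * nx + xx];
              if (lj && std::abs(lj - li) <= alpha) ++dep;
            }
        out(li - 1, dep - 1) += 1.0;
      }
  return out;
}

// Neighbourhood gray tone difference ingredients: per level, the count of
// contributing voxels n_i and the summed |i - A_i| where A_i is the mean
// level over valid 26-neighbours. Voxels with no valid neighbour are
// excluded.
// [[Rcpp::export]]
List cpp_ngtdm(IntegerVector labels, IntegerVector dims, int ng) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector nvec(ng);
  NumericVector svec(ng);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int li = labels[(z * ny + y) * nx + x];
        if (!li) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              const int xx = x + dx, yy = y + dy, zz = z + dz;
              if (!inside(xx, yy, zz, nx, ny, nz)) continue;
              const int lj = labels[(zz * ny + yy) * nx + xx];
              if (lj) {
                sum += lj;
                ++cnt;
              }
            }
        if (cnt > 0) {
          nvec[li - 1] += 1;
          svec[li - 1] += std::fabs(li - sum / cnt);
        }
      }
  return List::create(Named("n") = nvec, Named("s") = svec);
}
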