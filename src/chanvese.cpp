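#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static const int F6[6][3] = {{1, 0, 0},  {-1, 0, 0}, {0, 1, 0},
                             {0, -1, 0}, {0, 0, 1},  {0, 0, -1}};

// perimeter = total physical area of faces between region and non-region
static double perimeter(const std::vector<char> &reg, int nx, int ny, int nz,
                        const double fa[3]) {
  double p = 0.0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (!reg[(z * ny + y) * nx + x]) continue;
        for (int f = 0; f < 6; ++f) {
          const int xx = x + F6[f][0], yy = y + F6[f][1], zz = z + F6[f][2];
          bool nb = false;
          if (xx >= 0 && xx < nx && yy >= 0 && yy < ny && zz >= 0 && zz < nz)
            nb = reg[(zz * ny + yy) * nx + xx];
          if (!nb) p += fa[f / 2];
        }
      }
  return p;
}

// Two-region piecewise-constant (Chan-Vese type) energy of a labelling,
// restricted to the initial mask, with a boundary-length penalty lambda.
// [[Rcpp::export]]
double cpp_cv_energy(NumericVector img, LogicalVector init, LogicalVector region,
                     IntegerVector dims, NumericVector face_area,
                     double lambda) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  const double fa[3] = {face_area[0], face_area[1], face_area[2]};
  double s1 = 0, s2 = 0;
  int n1 = 0, n2 = 0;
  for (int i = 0; i < n; ++i) {
    if (!init[i]) continue;
    if (region[i]) { s1 += img[i]; ++n1; } else { s2 += img[i]; ++n2; }
  }
  const double c1 = n1 ? s1 / n1 : 0.0, c2 = n2 ? s2 / n2 : 0.0;
  double e = 0.0;
  std::vector<char> reg(n, 0);
  for (int i = 0; i < n; ++i) {
    if (!init[i]) continue;
    if (region[i]) {
      e += (img[i] - c1) * (img[i] - c1);
      reg[i] = 1;
    } else {
      e += (img[i] - c2) * (img[i] - c2);
    }
  }
  return e + lambda * perimeter(reg, nx, ny, nz, fa);
}

// Iterated-conditional-modes minimisation of the two-region
// piecewise-constant energy inside `init`, starting from `start`.
// Region means are refreshed after each full sweep; sweeps run in linear
// voxel order, so the result is deterministic.
// [[Rcpp::export]]
List cpp_chanvese_icm(NumericVector img, LogicalVector init,
                      LogicalVector start, IntegerVector dims,
                      NumericVector face_area, double lambda, int max_iter,
                      double tol) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  const double fa[3] = {face_area[0], face_area[1], face_area[2]};
  std::vector<char> reg(n, 0);
  std::vector<int> idx;
  for (int i = 0; i < n; ++i) {
    if (init[i]) idx.push_back(i);
    if (init[i] && start[i]) reg[i] = 1;
  }
  bool degenerate = false, converged = false;
  double e_prev = R_PosInf;
  int sweep = 0;
  for (sweep = 1; sweep <= max_iter; ++sweep) {
    double s1 = 0, s2 = 0;
    int n1 = 0, n2 = 0;
    for (int i : idx) {
      if (reg[i]) { s1 += img[i]; ++n1; } else { s2 += img[i]; ++n2; }
    }
    if (n1 == 0 || n2 == 0) { degenerate = true; break; }
    const double c1 = s1 / n1, c2 = s2 / n2;
    int flips = 0;
    for (int i : idx) {
      const int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
      // boundary-length change of adding voxel i to the region: faces to
      // in-region neighbours close (-fa), faces to the rest open (+fa);
      // removal is the exact mirror (-dperim_add). Own membership must be
      // ignored when scanning neighbours, so count others only.
      double dperim_add = 0.0;
      for (int f = 0; f < 6; ++f) {
        const int xx = x + F6[f][0], yy = y + F6[f][1], zz = z + F6[f][2];
        bool nb = false;
        if (xx >= 0 && xx < nx && yy >= 0 && yy < ny && zz >= 0 && zz < nz)
          nb = reg[(zz * ny + yy) * nx + xx];
        dperim_add += nb ? -fa[f / 2] : fa[f / 2];
      }
      const double d1 = (img[i] - c1) * (img[i] - c1);
      const double d2 = (img[i] - c2) * (img[i] - c2);
      double de;
      if (reg[i]) {
        de = (d2 - d1) - lambda * dperim_add;
      } else {
        de = (d1 - d2) + lambda * dperim_add;
      }
      if (de < -1e-12) {
        reg[i] = reg[i] ? 0 : 1;
        ++flips;
      }
    }
    // energy with refreshed means
    s1 = s2 = 0; n1 = n2 = 0;
    for (int i : idx) {
      if (reg[i]) { s1 += img[i]; ++n1; } else { s2 += img[i]; ++n2; }
    }
    if (n1 == 0 || n2 == 0) { degenerate = true; break; }
    const double m1 = s1 / n1, m2 = s2 / n2;
    double e = 0.0;
    for (int i : idx) {
      const double c = reg[i] ? m1 : m2;
      e += (img[i] - c) * (img[i] - c);
    }
    e += lambda * perimeter(reg, nx, ny, nz, fa);
    if (flips == 0 || std::fabs(e_prev - e) < tol) {
      converged = true;
      e_prev = e;
      break;
    }
    e_prev = e;
  }
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = reg[i] != 0;
  return List::create(Named("mask") = out, Named("iterations") = sweep,
                      Named("converged") = converged,
                      Named("degenerate") = degenerate,
                      Named("energy") = e_prev);
}
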