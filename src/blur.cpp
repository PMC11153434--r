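#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static void blur_axis(std::vector<double> &src, std::vector<double> &dst,
                      int nx, int ny, int nz, int axis, double sigma) {
  const int n = nx * ny * nz;
  if (sigma <= 0) { dst = src; return; }
  const int r = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> k(2 * r + 1);
  for (int t = -r; t <= r; ++t)
    k[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
  const int len = axis == 0 ? nx : (axis == 1 ? ny : nz);
  const int stride = axis == 0 ? 1 : (axis == 1 ? nx : nx * ny);
  for (int i = 0; i < n; ++i) {
    const int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
    const int pos = axis == 0 ? x : (axis == 1 ? y : z);
    double acc = 0.0, wsum = 0.0;
    const int lo = std::max(0, pos - r), hi = std::min(len - 1, pos + r);
    for (int t = lo; t <= hi; ++t) {
      const double w = k[t - pos + r];
      acc += w * src[i + (t - pos) * stride];
      wsum += w;
    }
    dst[i] = acc / wsum;  // truncated-kernel renormalisation: constants preserved
  }
}

// Separable Gaussian blur; sigma given in voxels per axis.
// [[Rcpp::export]]
NumericVector cpp_gauss_blur(NumericVector vol, IntegerVector dims,
                             NumericVector sigma_vox) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<double> a(vol.begin(), vol.end()), b(n);
  blur_axis(a, b, nx, ny, nz, 0, sigma_vox[0]);
  blur_axis(b, a, nx, ny, nz, 1, sigma_vox[1]);
  blur_axis(a, b, nx, ny, nz, 2, sigma_vox[2]);
  NumericVector out(n);
  std::copy(b.begin(), b.end(), out.begin());
  return out;
}
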