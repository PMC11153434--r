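#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Affinity propagation (Frey & Dueck message passing) on a dense
// similarity matrix with preferences already placed on the diagonal.
// Fully deterministic: ties resolve to the lowest index. Messages are kept
// in row-major buffers so the responsibility pass is contiguous.
// [[Rcpp::export]]
List cpp_affinity_propagation(NumericMatrix S, double damping, int maxit,
                              int convits) {
  const int n = S.nrow();
  std::vector<double> Sr((size_t)n * n), R((size_t)n * n, 0.0),
      A((size_t)n * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < n; ++k) Sr[(size_t)i * n + k] = S(i, k);
  std::vector<char> was_ex(n, 0);
  std::vector<double> col_pos(n), rkk(n);
  int stable = 0, it = 0;
  bool converged = false;
  const double keep = damping, upd = 1.0 - damping;
  for (it = 1; it <= maxit; ++it) {
    // responsibilities (row-contiguous)
    for (int i = 0; i < n; ++i) {
      double *Ai = &A[(size_t)i * n];
      double *Ri = &R[(size_t)i * n];
      const double *Si = &Sr[(size_t)i * n];
      double max1 = -1e300, max2 = -1e300;
      int argmax = -1;
      for (int k = 0; k < n; ++k) {
        const double v = Ai[k] + Si[k];
        if (v > max1) {
          max2 = max1;
          max1 = v;
          argmax = k;
        } else if (v > max2) {
          max2 = v;
        }
      }
      for (int k = 0; k < n; ++k)
        Ri[k] = keep * Ri[k] + upd * (Si[k] - (k == argmax ? max2 : max1));
    }
    // availabilities: first accumulate per-column positive responsibilities
    for (int k = 0; k < n; ++k) {
      col_pos[k] = 0.0;
      rkk[k] = R[(size_t)k * n + k];
    }
    for (int i = 0; i < n; ++i) {
      const double *Ri = &R[(size_t)i * n];
      for (int k = 0; k < n; ++k)
        if (i != k && Ri[k] > 0.0) col_pos[k] += Ri[k];
    }
    for (int i = 0; i < n; ++i) {
      double *Ai = &A[(size_t)i * n];
      const double *Ri = &R[(size_t)i * n];
      for (int k = 0; k < n; ++k) {
        double anew;
        if (i == k) {
          anew = col_pos[k];
        } else {
          anew = rkk[k] + col_pos[k] - (Ri[k] > 0.0 ? Ri[k] : 0.0);
          if (anew > 0.0) anew = 0.0;
        }
        Ai[k] = keep * Ai[k] + upd * anew;
      }
    }
    // exemplar stability
    bool same = true;
    int n_ex = 0;
    for (int k = 0; k < n; ++k) {
      const char ex =
          (A[(size_t)k * n + k] + R[(size_t)k * n + k]) > 0.0 ? 1 : 0;
      if (ex != was_ex[k]) same = false;
      was_ex[k] = ex;
      n_ex += ex;
    }
    stable = (same && n_ex > 0) ? stable + 1 : 0;
    if (stable >= convits) {
      converged = true;
      break;
    }
  }
  std::vector<int> exemplars;
  for (int k = 0; k < n; ++k)
    if (was_ex[k]) exemplars.push_back(k);
  IntegerVector assign(n, NA_INTEGER);
  if (!exemplars.empty()) {
    for (int i = 0; i < n; ++i) {
      double best = -1e300;
      int bk = exemplars[0];
      for (int e : exemplars) {
        const double v = Sr[(size_t)i * n + e];
        if (v > best) {
          best = v;
          bk = e;
        }
      }
      assign[i] = bk + 1;  // 1-based
    }
    for (int e : exemplars) assign[e] = e + 1;
  }
  return List::create(Named("assignment") = assign,
                      Named("converged") = converged,
                      Named("iterations") = it);
}
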