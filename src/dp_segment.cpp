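#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact least-squares change-point segmentation by dynamic programming.
//
// For every number of change-points k = 0..max_k, finds the placement of k
// breakpoints minimising the Gaussian residual sum of squares (RSS) of the
// piecewise-constant fit.  O(max_k * n^2) time, O(max_k * n) memory.
// Ties in the inner minimisation are broken towards the leftmost breakpoint
// (strict improvement required to move right), so results are deterministic.
//
// Returns, for each k, the optimal RSS and the breakpoint indices: a
// breakpoint b means a change between probes b and b+1 (1-based).
// [[Rcpp::export]]
List dp_segment_rss(NumericVector x, int max_k) {
  const int n = x.size();
  if (n < 1) stop("empty profile");
  if (max_k < 0) stop("max_k must be >= 0");
  if (max_k > n - 1) max_k = n - 1;

  std::vector<double> S(n + 1, 0.0), S2(n + 1, 0.0), inv(n + 1, 0.0);
  for (int i = 1; i <= n; ++i) {
    S[i]  = S[i - 1] + x[i - 1];
    S2[i] = S2[i - 1] + x[i - 1] * x[i - 1];
    inv[i] = 1.0 / (double)i;
  }

  // cur[i]: minimal RSS for probes 1..i with k change-points (k = loop var)
  // back[k*(n+1)+i]: position of the last breakpoint in that optimum
  std::vector<double> prev(n + 1, 0.0), cur(n + 1, 0.0);
  std::vector<int> back((size_t)(max_k + 1) * (n + 1), 0);
  NumericVector rss(max_k + 1);
  List bps(max_k + 1);

  for (int i = 1; i <= n; ++i) {
    const double s = S[i];
    const double v = S2[i] - s * s * inv[i];
    prev[i] = v > 0.0 ? v : 0.0;
  }
  rss[0] = prev[n];
  bps[0] = IntegerVector(0);

  std::vector<double> rss_k(max_k + 1, 0.0);
  rss_k[0] = prev[n];

  for (int k = 1; k <= max_k; ++k) {
    int* bk = &back[(size_t)k * (n + 1)];
    const double* Sp = S.data();
    const double* S2p = S2.data();
    const double* invp = inv.data();
    for (int i = 1; i <= n; ++i) {
      if (i < k + 1) { cur[i] = 0.0; bk[i] = i - 1; continue; }
      double best = R_PosInf;
      int arg = k;
      const double Si = Sp[i], S2i = S2p[i];
      for (int j = k; j <= i - 1; ++j) {
        const double s = Si - Sp[j];
        double seg = S2i - S2p[j] - s * s * invp[i - j];
        if (seg < 0.0) seg = 0.0;
        const double cand = prev[j] + seg;
        if (cand < best) { best = cand; arg = j; }
      }
      cur[i] = best;
      bk[i] = arg;
    }
    rss_k[k] = cur[n];
    std::swap(prev, cur);
  }

  for (int k = 0; k <= max_k; ++k) {
    rss[k] = rss_k[k];
    IntegerVector b(k);
    int pos = n;
    for (int kk = k; kk >= 1; --kk) {
      pos = back[(size_t)kk * (n + 1) + pos];
      b[kk - 1] = pos;
    }
    bps[k] = b;
  }
  return List::create(_["rss"] = rss, _["breakpoints"] = bps);
}
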