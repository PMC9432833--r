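#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Null-distribution dot products for the similarity statistic.
//
// For a binary behavior vector B with m ones, dot(perm(B), C) equals the sum
// of C at m positions drawn uniformly without replacement, so each shuffle
// costs O(m) via partial Fisher-Yates on a persistent index array (the array
// stays a permutation between draws, which preserves uniformity). Norms are
// permutation-invariant and handled by the caller.

// [[Rcpp::export]]
NumericVector perm_null_dot_binary(NumericVector C, int m, int k) {
  int n = C.size();
  if (m < 0 || m > n) stop("m must be in [0, length(C)]");
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  NumericVector out(k);
  for (int j = 0; j < k; ++j) {
    double s = 0.0;
    for (int i = 0; i < m; ++i) {
      int r = i + (int)(unif_rand() * (n - i));
      if (r >= n) r = n - 1;
      std::swap(idx[i], idx[r]);
      s += C[idx[i]];
    }
    out[j] = s;
  }
  return out;
}

// General (non-binary) B: full Fisher-Yates shuffle per draw, O(k*n).

// [[Rcpp::export]]
NumericVector perm_null_dot_full(NumericVector B, NumericVector C, int k) {
  int n = B.size();
  if (C.size() != n) stop("B and C must have equal length");
  std::vector<double> b(B.begin(), B.end());
  NumericVector out(k);
  for (int j = 0; j < k; ++j) {
    for (int i = n - 1; i > 0; --i) {
      int r = (int)(unif_rand() * (i + 1));
      if (r > i) r = i;
      std::swap(b[i], b[r]);
    }
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += b[i] * C[i];
    out[j] = s;
  }
  return out;
}
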