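#include <Rcpp.h>
using namespace Rcpp;

// Second-order-section IIR cascade, transposed direct form II, with explicit
// per-section/per-channel state so chunked (streaming) and whole-signal
// filtering are bit-identical. sos: nsec x 6 rows (b0 b1 b2 a0 a1 a2), a0 = 1.
// zi: (2*nsec) x nchan state matrix, updated in place on a copy and returned.
// [[Rcpp::export]]
List sos_filter_cpp(NumericMatrix x, NumericMatrix sos, NumericMatrix zi) {
  int n = x.nrow(), nc = x.ncol(), ns = sos.nrow();
  if (zi.nrow() != 2 * ns || zi.ncol() != nc)
    stop("state matrix must be (2*n_sections) x n_channels");
  NumericMatrix y(n, nc);
  NumericMatrix z = clone(zi);
  for (int c = 0; c < nc; ++c) {
    for (int i = 0; i < n; ++i) {
      double v = x(i, c);
      for (int s = 0; s < ns; ++s) {
        double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
        double a1 = sos(s, 4), a2 = sos(s, 5);
        double w = v;
        v = b0 * w + z(2 * s, c);
        z(2 * s, c) = b1 * w - a1 * v + z(2 * s + 1, c);
        z(2 * s + 1, c) = b2 * w - a2 * v;
      }
      y(i, c) = v;
    }
  }
  return List::create(_["y"] = y, _["zi"] = z);
}

// Plain Levenshtein distance between two integer sequences (two-row DP).
// [[Rcpp::export]]
int levenshtein_cpp(IntegerVector a, IntegerVector b) {
  int n = a.size(), m = b.size();
  if (n == 0) return m;
  if (m == 0) return n;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      cur[j] = std::min(sub, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Minimum-cost label path for per-frame costs nll (T x K) with a switching
// penalty beta added whenever consecutive labels differ. Forward dynamic
// program with backtracking; ties broken toward the lower cluster index.
// Returns 0-based labels.
// [[Rcpp::export]]
IntegerVector viterbi_assign_cpp(NumericMatrix nll, double beta) {
  int T = nll.nrow(), K = nll.ncol();
  IntegerVector path(T);
  if (T == 0) return path;
  std::vector<double> prev(K), cur(K);
  std::vector<int> bp(static_cast<size_t>(T) * K);
  for (int k = 0; k < K; ++k) prev[k] = nll(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      int arg = 0;
      double best = prev[0] + (0 == k ? 0.0 : beta);
      for (int j = 1; j < K; ++j) {
        double c = prev[j] + (j == k ? 0.0 : beta);
        if (c < best) { best = c; arg = j; }  // strict <: lowest index on ties
      }
      cur[k] = nll(t, k) + best;
      bp[static_cast<size_t>(t) * K + k] = arg;
    }
    prev = cur;
  }
  int kbest = 0;
  for (int k = 1; k < K; ++k) if (prev[k] < prev[kbest]) kbest = k;
  path[T - 1] = kbest;
  for (int t = T - 1; t > 0; --t)
    path[t - 1] = bp[static_cast<size_t>(t) * K + path[t]];
  return path;
}
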