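#include <Rcpp.h>
using namespace Rcpp;

// Score-only Needleman-Wunsch over integer-coded symbol sequences.
// a, b are 1-based indices into the substitution matrix; gap is the
// per-symbol gap contribution. Two-row rolling dynamic program.
static double nw_dp(const IntegerVector& a, const IntegerVector& b,
                    const NumericMatrix& sub, double gap) {
  const int n = a.size(), m = b.size();
  std::vector<double> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j * gap;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * gap;
    const int ai = a[i - 1] - 1;
    for (int j = 1; j <= m; ++j) {
      double diag = prev[j - 1] + sub(ai, b[j - 1] - 1);
      double up   = prev[j] + gap;
      double left = cur[j - 1] + gap;
      cur[j] = std::max(diag, std::max(up, left));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export(name = ".nw_score_cpp")]]
double nw_score_cpp(IntegerVector a, IntegerVector b,
                    NumericMatrix sub, double gap) {
  return nw_dp(a, b, sub, gap);
}

// All-pairs normalized similarity: nw(i, j) / max(len_i, len_j).
// [[Rcpp::export(name = ".similarity_matrix_cpp")]]
NumericMatrix similarity_matrix_cpp(List codes, NumericMatrix sub, double gap) {
  const int n = codes.size();
  std::vector<IntegerVector> seqs(n);
  for (int i = 0; i < n; ++i) seqs[i] = as<IntegerVector>(codes[i]);
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double L = std::max(seqs[i].size(), seqs[j].size());
      double s = nw_dp(seqs[i], seqs[j], sub, gap) / L;
      out(i, j) = s;
      out(j, i) = s;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
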