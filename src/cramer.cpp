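#include <Rcpp.h>
using namespace Rcpp;

// Baringhaus-Franz statistic from a pooled inter-point distance matrix.
// idx holds the 0-based positions of the first sample within the pool;
// the remaining positions form the second sample. Within-sample sums
// include the zero diagonal terms, divisors m^2 and n^2 as in the
// definition T = mn/(m+n) [ mean cross - mean_X/2 - mean_Y/2 ].
static double bf_stat(const NumericMatrix& D, const std::vector<int>& xi,
                      const std::vector<int>& yi) {
  const int m = xi.size(), n = yi.size();
  double cross = 0.0, wx = 0.0, wy = 0.0;
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j) cross += D(xi[i], yi[j]);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < m; ++j) wx += D(xi[i], xi[j]);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) wy += D(yi[i], yi[j]);
  double mn = (double)m * n;
  return mn / (m + n) *
         (cross / mn - wx / (2.0 * m * m) - wy / (2.0 * n * n));
}

// [[Rcpp::export(name = ".cramer_stat_idx_cpp")]]
double cramer_stat_idx_cpp(NumericMatrix D, IntegerVector x_idx) {
  const int N = D.nrow(), m = x_idx.size();
  std::vector<bool> inx(N, false);
  std::vector<int> xi, yi;
  for (int i = 0; i < m; ++i) { inx[x_idx[i] - 1] = true; xi.push_back(x_idx[i] - 1); }
  for (int i = 0; i < N; ++i) if (!inx[i]) yi.push_back(i);
  return bf_stat(D, xi, yi);
}

// Permutation null: `replicates` random reassignments of the pooled points
// into samples of size m and N - m. Uses the R RNG so results are
// reproducible under set.seed().
// [[Rcpp::export(name = ".cramer_perm_cpp")]]
NumericVector cramer_perm_cpp(NumericMatrix D, int m, int replicates) {
  const int N = D.nrow();
  NumericVector out(replicates);
  for (int r = 0; r < replicates; ++r) {
    IntegerVector perm = Rcpp::sample(N, N, false);
    std::vector<int> xi(m), yi(N - m);
    for (int i = 0; i < m; ++i) xi[i] = perm[i] - 1;
    for (int i = m; i < N; ++i) yi[i - m] = perm[i] - 1;
    out[r] = bf_stat(D, xi, yi);
    if (r % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
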