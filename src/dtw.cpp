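#include <Rcpp.h>
using namespace Rcpp;

// Classical dynamic time warping with absolute-difference local cost and
// steps {match, insert, delete}; unnormalized accumulated cost, no window.
// [[Rcpp::export(name = ".dtw_cpp")]]
double dtw_cpp(NumericVector a, NumericVector b) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("dtw: empty sequence");
  // rolling two-row DP
  std::vector<double> prev(m), cur(m);
  prev[0] = std::fabs(a[0] - b[0]);
  for (int j = 1; j < m; ++j) prev[j] = prev[j - 1] + std::fabs(a[0] - b[j]);
  for (int i = 1; i < n; ++i) {
    cur[0] = prev[0] + std::fabs(a[i] - b[0]);
    for (int j = 1; j < m; ++j) {
      double c = std::fabs(a[i] - b[j]);
      double best = prev[j - 1];            // match
      if (prev[j] < best) best = prev[j];   // insertion
      if (cur[j - 1] < best) best = cur[j - 1]; // deletion
      cur[j] = c + best;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}
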