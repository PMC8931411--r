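#include <Rcpp.h>
using namespace Rcpp;

// Classic dynamic-programming DTW with local cost |a_i - b_j| and the
// symmetric step pattern (match / insert / delete), no warping window and no
// normalization inside the recursion. Two-row rolling buffer keeps memory O(n).
// [[Rcpp::export(name = ".dtw_distance_cpp")]]
double dtw_distance_cpp(NumericVector a, NumericVector b) {
  const int m = a.size(), n = b.size();
  if (m == 0 || n == 0) stop("dtw_distance: both sequences must be non-empty");
  std::vector<double> prev(n + 1, R_PosInf), curr(n + 1, R_PosInf);
  prev[0] = 0.0;
  for (int i = 1; i <= m; ++i) {
    curr[0] = R_PosInf;
    const double ai = a[i - 1];
    for (int j = 1; j <= n; ++j) {
      const double cost = std::fabs(ai - b[j - 1]);
      double best = prev[j - 1];           // match
      if (prev[j] < best) best = prev[j];  // insertion
      if (curr[j - 1] < best) best = curr[j - 1];  // deletion
      curr[j] = cost + best;
    }
    std::swap(prev, curr);
  }
  return prev[n];
}

// DTW of one reference sequence against each column of a matrix of candidate
// sequences (all resampled to the same length); avoids R-level loop overhead
// when scoring a 5x5 neighborhood.
// [[Rcpp::export(name = ".dtw_distance_many_cpp")]]
NumericVector dtw_distance_many_cpp(NumericVector a, NumericMatrix B) {
  const int k = B.ncol();
  NumericVector out(k);
  for (int j = 0; j < k; ++j) {
    NumericVector bj = B(_, j);
    out[j] = dtw_distance_cpp(a, bj);
  }
  return out;
}
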