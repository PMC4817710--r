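#include <Rcpp.h>
using namespace Rcpp;

// Weighted per-column character tallies over a subset of rows of an
// integer-encoded sequence matrix (values 1..6 = A,C,G,T,N,-).
// Returns a 6 x L matrix of summed weights. This is the hot loop of
// entropy profiling: each node of the decomposition calls it once.
// [[Rcpp::export]]
NumericMatrix column_state_counts(const IntegerMatrix& U,
                                  const IntegerVector& rows,
                                  const NumericVector& w) {
  const int L = U.ncol();
  const int m = rows.size();
  if (w.size() != m) stop("rows and w must have equal length");
  NumericMatrix out(6, L);
  for (int r = 0; r < m; ++r) {
    const int i = rows[r] - 1;  // 1-based from R
    if (i < 0 || i >= U.nrow()) stop("row index out of range");
    const double wi = w[r];
    for (int j = 0; j < L; ++j) {
      const int s = U(i, j);
      if (s < 1 || s > 6) stop("sequence matrix values must be in 1..6");
      out(s - 1, j) += wi;
    }
  }
  return out;
}
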