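#include <Rcpp.h>
using namespace Rcpp;

// Scatter-add adjoint of the im2col gather: accumulates every element of
// `dcols` (column-major) into a zeroed buffer of length `out_len` at the
// 1-based positions in `idx` (same layout as the gather index). Duplicate
// targets are handled by the sequential accumulation.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericVector dcols, IntegerVector idx,
                         double out_len) {
  R_xlen_t n = dcols.size();
  if (idx.size() != n) stop("cpp_col2im: index/value length mismatch");
  NumericVector out((R_xlen_t) out_len);
  const int* ip = INTEGER(idx);
  const double* dp = REAL(dcols);
  double* op = REAL(out);
  for (R_xlen_t k = 0; k < n; ++k) op[ip[k] - 1] += dp[k];
  return out;
}

// Gather for im2col: out[k] = x[idx[k] - 1], avoiding the intermediate
// allocations of R-level subsetting on very large index vectors.
// [[Rcpp::export]]
NumericVector cpp_gather(NumericVector x, IntegerVector idx) {
  R_xlen_t n = idx.size();
  NumericVector out(n);
  const int* ip = INTEGER(idx);
  const double* xp = REAL(x);
  double* op = REAL(out);
  for (R_xlen_t k = 0; k < n; ++k) op[k] = xp[ip[k] - 1];
  return out;
}
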