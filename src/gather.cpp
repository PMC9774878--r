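#include <Rcpp.h>
using namespace Rcpp;

// Row gather with implicit zero padding: idx is 1-based into the rows of A,
// idx == 0 yields a zero row (used for 'same'-padded convolution im2col).
// [[Rcpp::export(name = ".gather_rows")]]
NumericMatrix gather_rows(const NumericMatrix& A, const IntegerVector& idx) {
  const R_xlen_t m = idx.size(), n = A.ncol();
  NumericMatrix out(m, n);
  const double* a = A.begin();
  double* o = out.begin();
  const R_xlen_t lda = A.nrow();
  for (R_xlen_t j = 0; j < n; ++j) {
    const double* aj = a + j * lda;
    double* oj = o + j * m;
    for (R_xlen_t i = 0; i < m; ++i) {
      const int k = idx[i];
      oj[i] = (k > 0) ? aj[k - 1] : 0.0;
    }
  }
  return out;
}

// Transpose of gather_rows: accumulate rows of D into an nout x ncol matrix
// at positions idx (1-based); idx == 0 rows are dropped (padding).
// [[Rcpp::export(name = ".scatter_rows_add")]]
NumericMatrix scatter_rows_add(const NumericMatrix& D, const IntegerVector& idx,
                               const int nout) {
  const R_xlen_t m = idx.size(), n = D.ncol();
  if (D.nrow() != m) stop("nrow(D) must equal length(idx)");
  NumericMatrix out(nout, n);
  const double* d = D.begin();
  double* o = out.begin();
  for (R_xlen_t j = 0; j < n; ++j) {
    const double* dj = d + j * m;
    double* oj = o + j * (R_xlen_t)nout;
    for (R_xlen_t i = 0; i < m; ++i) {
      const int k = idx[i];
      if (k > 0) oj[k - 1] += dj[i];
    }
  }
  return out;
}
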