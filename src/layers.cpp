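// Fused layer primitives for the CAE engine.  Activations are S x n
// matrices (column = example).  Convolutions take a precomputed im2col
// index (1-based, 0 = zero padding) and do gather + GEMM + bias +
// channel-transpose in one pass; the spectral 1x1 layers exploit the
// band-fastest / spatial-fastest layouts so that one side of each GEMM is
// a zero-copy view.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// gather rows of A (S_in x n) into im2col matrix (K x P*n)
static arma::mat im2col(const arma::mat& A, const IntegerVector& idx,
                        const int K, const int P) {
  const int n = A.n_cols;
  arma::mat cols(K, (size_t)P * n);
  const double* a = A.memptr();
  const size_t S = A.n_rows;
  double* c = cols.memptr();
  for (int j = 0; j < n; ++j) {
    const double* aj = a + (size_t)j * S;
    double* cj = c + (size_t)j * K * P;
    for (int t = 0; t < K * P; ++t) {
      const int k = idx[t];
      cj[t] = (k > 0) ? aj[k - 1] : 0.0;
    }
  }
  return cols;
}

// [[Rcpp::export(name = ".conv_fwd")]]
List conv_fwd(const arma::mat& A, const IntegerVector& idx, const int K,
              const int P, const arma::mat& W, const arma::vec& b) {
  const int n = A.n_cols, cout = W.n_rows;
  arma::mat cols = im2col(A, idx, K, P);
  arma::mat Z = W * cols;            // cout x (P*n)
  Z.each_col() += b;
  NumericMatrix out((size_t)P * cout, n);
  double* o = REAL(out);
  const double* z = Z.memptr();
  for (int j = 0; j < n; ++j)
    for (int p = 0; p < P; ++p) {
      const double* zc = z + ((size_t)j * P + p) * cout;
      double* oc = o + (size_t)j * P * cout + p;
      for (int c = 0; c < cout; ++c) oc[(size_t)c * P] = zc[c];
    }
  return List::create(_["out"] = out, _["cols"] = cols);
}

// [[Rcpp::export(name = ".conv_bwd")]]
List conv_bwd(const arma::mat& dout, const arma::mat& cols,
              const IntegerVector& idx, const arma::mat& W, const int P,
              const int S_in, const bool need_din) {
  const int n = dout.n_cols, cout = W.n_rows, K = W.n_cols;
  arma::mat dZ(cout, (size_t)P * n);
  const double* d = dout.memptr();
  double* z = dZ.memptr();
  for (int j = 0; j < n; ++j)
    for (int p = 0; p < P; ++p) {
      const double* dc = d + (size_t)j * P * cout + p;
      double* zc = z + ((size_t)j * P + p) * cout;
      for (int c = 0; c < cout; ++c) zc[c] = dc[(size_t)c * P];
    }
  arma::mat dW = dZ * cols.t();
  arma::vec db = arma::sum(dZ, 1);
  List res = List::create(_["dW"] = dW, _["db"] = db);
  if (need_din) {
    arma::mat dcols = W.t() * dZ;    // K x (P*n)
    NumericMatrix din(S_in, n);
    double* o = REAL(din);
    const double* dc = dcols.memptr();
    for (int j = 0; j < n; ++j) {
      double* oj = o + (size_t)j * S_in;
      const double* cj = dc + (size_t)j * K * P;
      for (int t = 0; t < K * P; ++t) {
        const int k = idx[t];
        if (k > 0) oj[k - 1] += cj[t];
      }
    }
    res["din"] = din;
  }
  return res;
}

// spectral mixing: input band-fastest (B*sp x n), output spatial-fastest
// (sp*cout x n); the input reshape is a zero-copy view
// [[Rcpp::export(name = ".smix_fwd")]]
NumericMatrix smix_fwd(const arma::mat& A, const int bands, const int sp,
                       const arma::mat& W, const arma::vec& b) {
  const int n = A.n_cols, cout = W.n_rows;
  const arma::mat Av(const_cast<double*>(A.memptr()), bands,
                     (size_t)sp * n, false, true);
  arma::mat Z = W * Av;
  Z.each_col() += b;
  NumericMatrix out((size_t)sp * cout, n);
  double* o = REAL(out);
  const double* z = Z.memptr();
  for (int j = 0; j < n; ++j)
    for (int p = 0; p < sp; ++p) {
      const double* zc = z + ((size_t)j * sp + p) * cout;
      double* oc = o + (size_t)j * sp * cout + p;
      for (int c = 0; c < cout; ++c) oc[(size_t)c * sp] = zc[c];
    }
  return out;
}

// [[Rcpp::export(name = ".smix_bwd")]]
List smix_bwd(const arma::mat& dout, const arma::mat& A, const int bands,
              const int sp, const arma::mat& W, const bool need_din) {
  const int n = dout.n_cols, cout = W.n_rows;
  arma::mat dZ(cout, (size_t)sp * n);
  const double* d = dout.memptr();
  double* z = dZ.memptr();
  for (int j = 0; j < n; ++j)
    for (int p = 0; p < sp; ++p) {
      const double* dc = d + (size_t)j * sp * cout + p;
      double* zc = z + ((size_t)j * sp + p) * cout;
      for (int c = 0; c < cout; ++c) zc[c] = dc[(size_t)c * sp];
    }
  const arma::mat Av(const_cast<double*>(A.memptr()), bands,
                     (size_t)sp * n, false, true);
  arma::mat dW = dZ * Av.t();
  arma::vec db = arma::sum(dZ, 1);
  List res = List::create(_["dW"] = dW, _["db"] = db);
  if (need_din) {
    arma::mat din = W.t() * dZ;      // bands x (sp*n) == (bands*sp) x n
    din.reshape((size_t)bands * sp, n);
    res["din"] = din;
  }
  return res;
}

// spectral synthesis: input spatial-fastest (sp*cin x n), output
// band-fastest (bands*sp x n)
// [[Rcpp::export(name = ".ssynth_fwd")]]
List ssynth_fwd(const arma::mat& A, const int cin, const int sp,
                const arma::mat& W, const arma::vec& b) {
  const int n = A.n_cols, bands = W.n_rows;
  arma::mat Am(cin, (size_t)sp * n);
  const double* a = A.memptr();
  double* m = Am.memptr();
  for (int j = 0; j < n; ++j)
    for (int p = 0; p < sp; ++p) {
      const double* ac = a + (size_t)j * sp * cin + p;
      double* mc = m + ((size_t)j * sp + p) * cin;
      for (int c = 0; c < cin; ++c) mc[c] = ac[(size_t)c * sp];
    }
  NumericMatrix out((size_t)bands * sp, n);
  arma::mat Zv(REAL(out), bands, (size_t)sp * n, false, true);
  Zv = W * Am;                       // bands x (sp*n) == (bands*sp) x n
  Zv.each_col() += b;
  return List::create(_["out"] = out, _["cache"] = Am);
}

// [[Rcpp::export(name = ".ssynth_bwd")]]
List ssynth_bwd(const arma::mat& dout, const arma::mat& Am, const int cin,
                const int sp, const arma::mat& W, const bool need_din) {
  const int n = dout.n_cols, bands = W.n_rows;
  const arma::mat dZ(const_cast<double*>(dout.memptr()), bands,
                     (size_t)sp * n, false, true);
  arma::mat dW = dZ * Am.t();
  arma::vec db = arma::sum(dZ, 1);
  List res = List::create(_["dW"] = dW, _["db"] = db);
  if (need_din) {
    arma::mat dc = W.t() * dZ;       // cin x (sp*n)
    NumericMatrix din((size_t)sp * cin, n);
    double* o = REAL(din);
    const double* d = dc.memptr();
    for (int j = 0; j < n; ++j)
      for (int p = 0; p < sp; ++p) {
        const double* dcol = d + ((size_t)j * sp + p) * cin;
        double* oc = o + (size_t)j * sp * cin + p;
        for (int c = 0; c < cin; ++c) oc[(size_t)c * sp] = dcol[c];
      }
    res["din"] = din;
  }
  return res;
}

// [[Rcpp::export(name = ".relu_fwd")]]
NumericMatrix relu_fwd(const NumericMatrix& A) {
  NumericMatrix out(A.nrow(), A.ncol());
  const double* a = A.begin();
  double* o = out.begin();
  const R_xlen_t len = (R_xlen_t)A.nrow() * A.ncol();
  for (R_xlen_t i = 0; i < len; ++i) o[i] = a[i] > 0 ? a[i] : 0.0;
  return out;
}

// backward through relu given the forward OUTPUT (zero iff inactive)
// [[Rcpp::export(name = ".relu_bwd")]]
NumericMatrix relu_bwd(const NumericMatrix& dout, const NumericMatrix& out) {
  NumericMatrix din(dout.nrow(), dout.ncol());
  const double* d = dout.begin();
  const double* o = out.begin();
  double* r = din.begin();
  const R_xlen_t len = (R_xlen_t)dout.nrow() * dout.ncol();
  for (R_xlen_t i = 0; i < len; ++i) r[i] = o[i] > 0 ? d[i] : 0.0;
  return din;
}
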