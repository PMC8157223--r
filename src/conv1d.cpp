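// 1-D convolution kernels for the descriptor networks.
// Data layout matches the R side: cubes are (channels, time, batch).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// valid cross-correlation along time, stride >= 1
// X: (C, T, B); W: (F, C, K); returns (F, Tout, B) pre-activation
// [[Rcpp::export]]
arma::cube conv1d_forward(const arma::cube& X, const arma::cube& W,
                          const arma::vec& b, const int stride) {
  const int C = X.n_rows, T = X.n_cols, B = X.n_slices;
  const int F = W.n_rows, K = W.n_slices;
  const int Tout = (T - K) / stride + 1;
  // W as (F, C*K)
  mat W2(F, C * K);
  for (int k = 0; k < K; ++k) W2.cols(k * C, (k + 1) * C - 1) = W.slice(k);
  cube out(F, Tout, B);
  mat col(C * K, Tout);
  for (int s = 0; s < B; ++s) {
    const mat& Xs = X.slice(s);
    for (int k = 0; k < K; ++k) {
      if (stride == 1) {
        col.rows(k * C, (k + 1) * C - 1) = Xs.cols(k, k + Tout - 1);
      } else {
        for (int t = 0; t < Tout; ++t) {
          col.submat(k * C, t, (k + 1) * C - 1, t) = Xs.col(t * stride + k);
        }
      }
    }
    mat Y = W2 * col;
    Y.each_col() += b;
    out.slice(s) = Y;
  }
  return out;
}

// backward pass; dZ already masked by the activation derivative
// returns list(dX, dW, db)
// [[Rcpp::export]]
Rcpp::List conv1d_backward(const arma::cube& X, const arma::cube& W,
                           const arma::cube& dZ, const int stride) {
  const int C = X.n_rows, T = X.n_cols, B = X.n_slices;
  const int F = W.n_rows, K = W.n_slices;
  const int Tout = dZ.n_cols;
  mat W2(F, C * K);
  for (int k = 0; k < K; ++k) W2.cols(k * C, (k + 1) * C - 1) = W.slice(k);
  mat dW2(F, C * K, fill::zeros);
  vec db(F, fill::zeros);
  cube dX(C, T, B, fill::zeros);
  mat col(C * K, Tout);
  for (int s = 0; s < B; ++s) {
    const mat& Xs = X.slice(s);
    for (int k = 0; k < K; ++k) {
      if (stride == 1) {
        col.rows(k * C, (k + 1) * C - 1) = Xs.cols(k, k + Tout - 1);
      } else {
        for (int t = 0; t < Tout; ++t) {
          col.submat(k * C, t, (k + 1) * C - 1, t) = Xs.col(t * stride + k);
        }
      }
    }
    const mat& dZs = dZ.slice(s);
    dW2 += dZs * col.t();
    db += sum(dZs, 1);
    mat dcol = W2.t() * dZs;          // (C*K, Tout)
    mat& dXs = dX.slice(s);
    for (int k = 0; k < K; ++k) {
      if (stride == 1) {
        dXs.cols(k, k + Tout - 1) += dcol.rows(k * C, (k + 1) * C - 1);
      } else {
        for (int t = 0; t < Tout; ++t) {
          dXs.col(t * stride + k) += dcol.submat(k * C, t, (k + 1) * C - 1, t);
        }
      }
    }
  }
  cube dW(F, C, K);
  for (int k = 0; k < K; ++k) dW.slice(k) = dW2.cols(k * C, (k + 1) * C - 1);
  return Rcpp::List::create(Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db,
                            Rcpp::Named("dX") = dX);
}
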