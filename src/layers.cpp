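// Hot kernels of the 1D convolutional network. Same-padding, stride-1
// convolution is evaluated as a sum of shifted GEMMs (one per kernel
// offset), which avoids materializing an im2col buffer; max pooling is
// window 2, stride 2. Activations are channel-first: cube
// (channels, length, batch).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
arma::cube conv1d_fw(const arma::cube& X, const arma::mat& W,
                     const arma::vec& b) {
  const int Cin = X.n_rows, L = X.n_cols, B = X.n_slices;
  const int Cout = W.n_cols, k = W.n_rows / Cin, half = (k - 1) / 2;
  cube Y(Cout, L, B);
  for (int s = 0; s < B; ++s) {
    mat& Ys = Y.slice(s);
    Ys.each_col() = b;
    const mat& Xs = X.slice(s);
    for (int j = 0; j < k; ++j) {
      const int off = j - half; // source position = target + off
      const int d0 = std::max(0, -off), d1 = std::min(L - 1, L - 1 - off);
      if (d1 < d0) continue;
      Ys.cols(d0, d1) +=
        W.rows(j * Cin, j * Cin + Cin - 1).t() * Xs.cols(d0 + off, d1 + off);
    }
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List conv1d_bw(const arma::cube& X, const arma::mat& W,
                     const arma::cube& dY, bool need_dx) {
  const int Cin = X.n_rows, L = X.n_cols, B = X.n_slices;
  const int Cout = W.n_cols, k = W.n_rows / Cin, half = (k - 1) / 2;
  mat dW(W.n_rows, Cout, fill::zeros);
  vec db(Cout, fill::zeros);
  cube dX(Cin, L, B);
  if (need_dx) dX.zeros();
  for (int s = 0; s < B; ++s) {
    const mat& Xs = X.slice(s);
    const mat& dYs = dY.slice(s);
    db += sum(dYs, 1);
    for (int j = 0; j < k; ++j) {
      const int off = j - half;
      const int d0 = std::max(0, -off), d1 = std::min(L - 1, L - 1 - off);
      if (d1 < d0) continue;
      dW.rows(j * Cin, j * Cin + Cin - 1) +=
        Xs.cols(d0 + off, d1 + off) * dYs.cols(d0, d1).t();
      if (need_dx)
        dX.slice(s).cols(d0 + off, d1 + off) +=
          W.rows(j * Cin, j * Cin + Cin - 1) * dYs.cols(d0, d1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
Rcpp::List maxpool2_fw(const arma::cube& X) {
  const int C = X.n_rows, L = X.n_cols, B = X.n_slices;
  const int Lo = L / 2;
  if (Lo < 1) Rcpp::stop("max-pooling input length < 2");
  cube Y(C, Lo, B);
  cube A(C, Lo, B); // 0 if left element of the pair won, 1 otherwise
  for (int s = 0; s < B; ++s)
    for (int l = 0; l < Lo; ++l)
      for (int c = 0; c < C; ++c) {
        const double a = X(c, 2 * l, s), b = X(c, 2 * l + 1, s);
        if (a >= b) { Y(c, l, s) = a; A(c, l, s) = 0.0; }
        else        { Y(c, l, s) = b; A(c, l, s) = 1.0; }
      }
  return Rcpp::List::create(Rcpp::Named("Y") = Y, Rcpp::Named("argmax") = A);
}

// [[Rcpp::export]]
arma::cube maxpool2_bw(const arma::cube& dY, const arma::cube& argmax,
                       int L) {
  const int C = dY.n_rows, Lo = dY.n_cols, B = dY.n_slices;
  cube dX(C, L, B, fill::zeros);
  for (int s = 0; s < B; ++s)
    for (int l = 0; l < Lo; ++l)
      for (int c = 0; c < C; ++c)
        dX(c, 2 * l + (int)argmax(c, l, s), s) = dY(c, l, s);
  return dX;
}
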