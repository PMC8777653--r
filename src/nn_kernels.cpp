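// BLAS-backed kernels for the 1D CNN engine.
//
// Batch activations are (B * L) x C matrices with sample-major row blocks.
// Convolutions use the tap-wise formulation: for kernel tap j the padded
// input rows [j, j + L) of each sample multiply the j-th Cin x Cout slice
// of the weight matrix, so no im2col matrix is ever materialised.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// same-padding, stride-1 1D convolution forward.
// A: (B*L) x Cin; W: (k*Cin) x Cout; b: Cout.
// [[Rcpp::export(name = ".conv1d_fwd")]]
arma::mat conv1d_fwd(const arma::mat& A, int L, int B, const arma::mat& W,
                     const arma::vec& b, int k) {
  const int Cin = A.n_cols, Cout = W.n_cols;
  const int pl = (k - 1) / 2, Lp = L + k - 1;
  mat out(B * L, Cout);
  mat Ap(Lp, Cin);
  mat o(L, Cout);
  for (int s = 0; s < B; ++s) {
    Ap.zeros();
    Ap.rows(pl, pl + L - 1) = A.rows(s * L, s * L + L - 1);
    o.zeros();
    for (int j = 0; j < k; ++j) {
      o += Ap.rows(j, j + L - 1) * W.rows(j * Cin, (j + 1) * Cin - 1);
    }
    o.each_row() += b.t();
    out.rows(s * L, s * L + L - 1) = o;
  }
  return out;
}

// [[Rcpp::export(name = ".conv1d_bwd")]]
Rcpp::List conv1d_bwd(const arma::mat& A, const arma::mat& dZ, int L, int B,
                      const arma::mat& W, int k) {
  const int Cin = A.n_cols, Cout = W.n_cols;
  const int pl = (k - 1) / 2, Lp = L + k - 1;
  mat dW(W.n_rows, Cout, fill::zeros);
  vec db = sum(dZ, 0).t();
  mat dA(B * L, Cin);
  mat Ap(Lp, Cin), dAp(Lp, Cin);
  for (int s = 0; s < B; ++s) {
    Ap.zeros();
    Ap.rows(pl, pl + L - 1) = A.rows(s * L, s * L + L - 1);
    const mat dZs = dZ.rows(s * L, s * L + L - 1);
    dAp.zeros();
    for (int j = 0; j < k; ++j) {
      dW.rows(j * Cin, (j + 1) * Cin - 1) +=
        Ap.rows(j, j + L - 1).t() * dZs;
      dAp.rows(j, j + L - 1) +=
        dZs * W.rows(j * Cin, (j + 1) * Cin - 1).t();
    }
    dA.rows(s * L, s * L + L - 1) = dAp.rows(pl, pl + L - 1);
  }
  return Rcpp::List::create(Rcpp::Named("dA") = dA,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// batch normalisation forward over rows (per column), with the moment
// source chosen by the caller: batch moments in training, running moments
// in evaluation.
// [[Rcpp::export(name = ".bn_fwd")]]
Rcpp::List bn_fwd_cpp(const arma::mat& A, const arma::vec& gamma,
                      const arma::vec& beta, const arma::vec& mu,
                      const arma::vec& v, double eps) {
  const int n = A.n_rows;
  vec inv_sd = 1.0 / sqrt(v + eps);
  mat xhat = A;
  xhat.each_row() -= mu.t();
  xhat.each_row() %= inv_sd.t();
  mat out = xhat;
  out.each_row() %= gamma.t();
  out.each_row() += beta.t();
  (void)n;
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("inv_sd") = inv_sd);
}

// [[Rcpp::export(name = ".bn_bwd")]]
Rcpp::List bn_bwd_cpp(const arma::mat& dout, const arma::vec& gamma,
                      const arma::mat& xhat, const arma::vec& inv_sd) {
  const double n = dout.n_rows;
  vec dgamma = sum(dout % xhat, 0).t();
  vec dbeta = sum(dout, 0).t();
  mat dxhat = dout;
  dxhat.each_row() %= gamma.t();
  rowvec s1 = sum(dxhat, 0) / n;
  rowvec s2 = sum(dxhat % xhat, 0) / n;
  mat dA = dxhat;
  dA.each_row() -= s1;
  dA -= xhat.each_row() % s2;
  dA.each_row() %= inv_sd.t();
  return Rcpp::List::create(Rcpp::Named("dA") = dA,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}
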