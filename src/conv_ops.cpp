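// Hot kernels of the ConvNet engine: im2col convolution and the
// locally connected (unshared-weight 1x1) layer, forward and backward.
// Activation layout matches R/nn_engine.R: feature-major C x (N*HW)
// matrices whose columns are position blocks of N samples; `src` is the
// conv source-position table (k9 x HW, 1-based, HW+1 = zero pad).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static mat im2col_blocks(const mat& x, const imat& src, const int N,
                         const int HW) {
  const int Cin = x.n_rows, k9 = src.n_rows;
  mat x2(k9 * Cin, (uword)N * HW);
  for (int k = 0; k < k9; ++k) {
    for (int p = 0; p < HW; ++p) {
      const int sp = src(k, p);  // 1-based; HW+1 = pad
      if (sp > HW) {
        x2.submat(k * Cin, (uword)p * N, (k + 1) * Cin - 1,
                  (uword)(p + 1) * N - 1).zeros();
      } else {
        x2.submat(k * Cin, (uword)p * N, (k + 1) * Cin - 1,
                  (uword)(p + 1) * N - 1) =
            x.cols((uword)(sp - 1) * N, (uword)sp * N - 1);
      }
    }
  }
  return x2;
}

// [[Rcpp::export(name = ".conv_fwd")]]
arma::mat conv_fwd_cpp(const arma::mat& x, const arma::mat& W,
                       const arma::vec& b, const arma::imat& src,
                       const int N, const int HW) {
  mat out = W * im2col_blocks(x, src, N, HW);
  out.each_col() += b;
  return out;
}

// [[Rcpp::export(name = ".conv_bwd")]]
Rcpp::List conv_bwd_cpp(const arma::mat& x, const arma::mat& W,
                        const arma::mat& dout, const arma::imat& src,
                        const int N, const int HW) {
  const int Cin = x.n_rows, k9 = src.n_rows;
  mat x2 = im2col_blocks(x, src, N, HW);
  mat dW = dout * x2.t();
  vec db = sum(dout, 1);
  mat dx2 = W.t() * dout;
  mat dx(Cin, (uword)N * HW, fill::zeros);
  for (int k = 0; k < k9; ++k) {
    for (int p = 0; p < HW; ++p) {
      const int sp = src(k, p);
      if (sp > HW) continue;
      dx.cols((uword)(sp - 1) * N, (uword)sp * N - 1) +=
          dx2.submat(k * Cin, (uword)p * N, (k + 1) * Cin - 1,
                     (uword)(p + 1) * N - 1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db,
                            Rcpp::Named("dx") = dx);
}

// [[Rcpp::export(name = ".local_fwd")]]
arma::mat local_fwd_cpp(const arma::mat& x, const arma::cube& W,
                        const arma::mat& b, const int N, const int HW) {
  mat out(W.n_rows, x.n_cols);
  for (int p = 0; p < HW; ++p) {
    out.cols((uword)p * N, (uword)(p + 1) * N - 1) =
        W.slice(p) * x.cols((uword)p * N, (uword)(p + 1) * N - 1);
    out.cols((uword)p * N, (uword)(p + 1) * N - 1).each_col() += b.col(p);
  }
  return out;
}

// [[Rcpp::export(name = ".local_bwd")]]
Rcpp::List local_bwd_cpp(const arma::mat& x, const arma::cube& W,
                         const arma::mat& dout, const int N,
                         const int HW) {
  cube dW(W.n_rows, W.n_cols, W.n_slices);
  mat db(W.n_rows, HW);
  mat dx(W.n_cols, x.n_cols);
  for (int p = 0; p < HW; ++p) {
    const uword c0 = (uword)p * N, c1 = (uword)(p + 1) * N - 1;
    dW.slice(p) = dout.cols(c0, c1) * x.cols(c0, c1).t();
    db.col(p) = sum(dout.cols(c0, c1), 1);
    dx.cols(c0, c1) = W.slice(p).t() * dout.cols(c0, c1);
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db,
                            Rcpp::Named("dx") = dx);
}

// Fused batch-norm + affine forward: (x - mu) * inv_sd * gamma + beta,
// per row. Returns the normalised xhat in `xhat` (in/out argument
// avoided; returned as a list to keep R semantics clean).
// [[Rcpp::export(name = ".bn_fwd")]]
Rcpp::List bn_fwd_cpp(const arma::mat& x, const arma::vec& mu,
                      const arma::vec& inv_sd, const arma::vec& gamma,
                      const arma::vec& beta) {
  mat xhat = x;
  xhat.each_col() -= mu;
  xhat.each_col() %= inv_sd;
  mat out = xhat;
  out.each_col() %= gamma;
  out.each_col() += beta;
  return Rcpp::List::create(Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("out") = out);
}
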