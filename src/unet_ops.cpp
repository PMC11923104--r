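// Low-level tensor primitives for the valid-convolution U-Net: unpadded
// k x k convolution (forward/backward, im2col + GEMM), 2x2 max pooling
// and 2x2-stride-2 transpose convolution.  Feature maps are H x W x C
// cubes (channels = slices); convolution weights are (Cout) x (Cin*k*k)
// matrices with patch layout (kr fastest, then kc, then channel);
// transpose-convolution weights are (Cout) x (Cin*4) with the four
// quadrant blocks [dr + 2*dc] side by side.
//
// The im2col buffer keeps patches in ROWS ((Ho*Wo) x (C*k*k)) so that
// every copy in/out of it touches a contiguous Armadillo column and the
// GEMMs use lazy transposes; this is what makes CPU training viable.

#define ARMA_NO_DEBUG
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using namespace arma;

static mat im2col(const cube& x, int k) {
  const int Ho = x.n_rows - k + 1, Wo = x.n_cols - k + 1, C = x.n_slices;
  mat cols((uword)Ho * Wo, C * k * k);
  for (int c = 0; c < C; ++c)
    for (int kc = 0; kc < k; ++kc)
      for (int kr = 0; kr < k; ++kr)
        cols.col(c * k * k + kc * k + kr) = vectorise(
          x.slice(c).submat(kr, kc, kr + Ho - 1, kc + Wo - 1));
  return cols;
}

// [[Rcpp::export]]
arma::cube conv_fwd_cpp(const arma::cube& x, const arma::mat& W,
                        const arma::vec& b, int k) {
  const int Ho = x.n_rows - k + 1, Wo = x.n_cols - k + 1;
  const int Cout = W.n_rows;
  if ((int)W.n_cols != (int)x.n_slices * k * k)
    stop("conv_fwd: weight shape does not match input channels");
  mat Y = im2col(x, k) * W.t();          // (Ho*Wo) x Cout
  Y.each_row() += b.t();
  cube y(Ho, Wo, Cout);
  for (int co = 0; co < Cout; ++co)
    y.slice(co) = reshape(Y.col(co), Ho, Wo);
  return y;
}

// [[Rcpp::export]]
List conv_bwd_cpp(const arma::cube& x, const arma::mat& W,
                  const arma::cube& dy, int k) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, Cout = dy.n_slices;
  const int C = x.n_slices;
  mat dY((uword)Ho * Wo, Cout);
  for (int co = 0; co < Cout; ++co)
    dY.col(co) = vectorise(dy.slice(co));
  mat cols = im2col(x, k);
  mat dW = dY.t() * cols;                // Cout x (C*k*k)
  vec db = sum(dY, 0).t();
  mat dcols = dY * W;                    // (Ho*Wo) x (C*k*k)
  cube dx(x.n_rows, x.n_cols, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int kc = 0; kc < k; ++kc)
      for (int kr = 0; kr < k; ++kr)
        dx.slice(c).submat(kr, kc, kr + Ho - 1, kc + Wo - 1) +=
          reshape(dcols.col(c * k * k + kc * k + kr), Ho, Wo);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
List maxpool_fwd_cpp(const arma::cube& x) {
  if (x.n_rows % 2 || x.n_cols % 2)
    stop("maxpool: spatial size must be even");
  const int Ho = x.n_rows / 2, Wo = x.n_cols / 2, C = x.n_slices;
  cube y(Ho, Wo, C);
  cube idx(Ho, Wo, C);  // 0..3 = (dr, dc) as dr + 2*dc
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double best = x(2 * i, 2 * j, c);
        int arg = 0;
        for (int dc = 0; dc < 2; ++dc)
          for (int dr = 0; dr < 2; ++dr) {
            const double v = x(2 * i + dr, 2 * j + dc, c);
            if (v > best) { best = v; arg = dr + 2 * dc; }
          }
        y(i, j, c) = best;
        idx(i, j, c) = arg;
      }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube maxpool_bwd_cpp(const arma::cube& dy, const arma::cube& idx) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, C = dy.n_slices;
  cube dx(2 * Ho, 2 * Wo, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const int a = (int)idx(i, j, c);
        dx(2 * i + (a % 2), 2 * j + (a / 2), c) = dy(i, j, c);
      }
  return dx;
}

// [[Rcpp::export]]
arma::cube upconv_fwd_cpp(const arma::cube& x, const arma::mat& W,
                          const arma::vec& b) {
  const int Hi = x.n_rows, Wi = x.n_cols, Cin = x.n_slices;
  const int Cout = W.n_rows;
  if ((int)W.n_cols != 4 * Cin)
    stop("upconv_fwd: weight shape does not match input channels");
  mat X((uword)Hi * Wi, Cin);
  for (int c = 0; c < Cin; ++c) X.col(c) = vectorise(x.slice(c));
  cube y(2 * Hi, 2 * Wi, Cout);
  for (int p = 0; p < 4; ++p) {
    const int dr = p % 2, dc = p / 2;
    mat Yp = X * W.cols(p * Cin, (p + 1) * Cin - 1).t();  // (Hi*Wi) x Cout
    Yp.each_row() += b.t();
    for (int co = 0; co < Cout; ++co) {
      const double* src = Yp.colptr(co);
      for (int j = 0; j < Wi; ++j)
        for (int i = 0; i < Hi; ++i)
          y(2 * i + dr, 2 * j + dc, co) = src[(uword)j * Hi + i];
    }
  }
  return y;
}

// [[Rcpp::export]]
List upconv_bwd_cpp(const arma::cube& x, const arma::mat& W,
                    const arma::cube& dy) {
  const int Hi = x.n_rows, Wi = x.n_cols, Cin = x.n_slices;
  const int Cout = dy.n_slices;
  mat X((uword)Hi * Wi, Cin);
  for (int c = 0; c < Cin; ++c) X.col(c) = vectorise(x.slice(c));
  mat dW(Cout, 4 * Cin, fill::zeros);
  vec db(Cout, fill::zeros);
  mat dX((uword)Hi * Wi, Cin, fill::zeros);
  mat dYp((uword)Hi * Wi, Cout);
  for (int p = 0; p < 4; ++p) {
    const int dr = p % 2, dc = p / 2;
    for (int co = 0; co < Cout; ++co) {
      double* dst = dYp.colptr(co);
      for (int j = 0; j < Wi; ++j)
        for (int i = 0; i < Hi; ++i)
          dst[(uword)j * Hi + i] = dy(2 * i + dr, 2 * j + dc, co);
    }
    dW.cols(p * Cin, (p + 1) * Cin - 1) = dYp.t() * X;
    db += sum(dYp, 0).t();
    dX += dYp * W.cols(p * Cin, (p + 1) * Cin - 1);
  }
  cube dx(Hi, Wi, Cin);
  for (int c = 0; c < Cin; ++c)
    dx.slice(c) = reshape(dX.col(c), Hi, Wi);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}
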