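// Convolution and max-pooling kernels for the small CNN. Convolution is
// implemented as im2col followed by a BLAS matrix multiply; the backward
// pass reuses the same patch layout. Layouts:
//   images/feature maps: arma::cube H x W x C (column-major slices)
//   patch matrix X:      (H' * W') rows, (kh * kw * C) cols, where the
//                        patch row index is i + j * H' (output pixel
//                        (i, j)) and the column index is
//                        (c * kw + dj) * kh + di
//   conv weights W:      (kh * kw * C) x F, bias: F

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat im2col(const cube& input, int kh, int kw) {
  const int H = input.n_rows, W = input.n_cols, C = input.n_slices;
  const int Ho = H - kh + 1, Wo = W - kw + 1;
  mat X(Ho * Wo, kh * kw * C);
  for (int c = 0; c < C; ++c) {
    const mat& sl = input.slice(c);
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int col = (c * kw + dj) * kh + di;
        // copy the Ho x Wo shifted block column by column
        for (int j = 0; j < Wo; ++j) {
          X.col(col).subvec(j * Ho, j * Ho + Ho - 1) =
            sl.col(j + dj).subvec(di, di + Ho - 1);
        }
      }
    }
  }
  return X;
}

// [[Rcpp::export]]
arma::cube conv_fwd(const arma::cube& input, const arma::mat& W,
                    const arma::vec& b, int kh, int kw) {
  const int Ho = input.n_rows - kh + 1, Wo = input.n_cols - kw + 1;
  mat X = im2col(input, kh, kw);
  mat out = X * W;
  out.each_row() += b.t();
  cube res(Ho, Wo, W.n_cols);
  for (unsigned f = 0; f < W.n_cols; ++f)
    res.slice(f) = reshape(out.col(f), Ho, Wo);
  return res;
}

// [[Rcpp::export]]
Rcpp::List conv_bwd(const arma::cube& input, const arma::mat& W,
                    const arma::cube& gout, int kh, int kw) {
  const int H = input.n_rows, Wd = input.n_cols, C = input.n_slices;
  const int Ho = gout.n_rows, Wo = gout.n_cols, F = gout.n_slices;
  mat X = im2col(input, kh, kw);
  mat G(Ho * Wo, F);
  for (int f = 0; f < F; ++f) G.col(f) = vectorise(gout.slice(f));
  mat dW = X.t() * G;
  vec db = sum(G, 0).t();
  mat dX = G * W.t();           // (Ho*Wo) x (kh*kw*C)
  cube dinput(H, Wd, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& sl = dinput.slice(c);
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int col = (c * kw + dj) * kh + di;
        for (int j = 0; j < Wo; ++j) {
          sl.col(j + dj).subvec(di, di + Ho - 1) +=
            dX.col(col).subvec(j * Ho, j * Ho + Ho - 1);
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db,
                            Rcpp::Named("dinput") = dinput);
}

// [[Rcpp::export]]
Rcpp::List maxpool_fwd(const arma::cube& input, int pool, int stride) {
  const int H = input.n_rows, W = input.n_cols, C = input.n_slices;
  const int Ho = (H - pool) / stride + 1, Wo = (W - pool) / stride + 1;
  cube out(Ho, Wo, C);
  ucube arg(Ho, Wo, C);         // linear index into the input cube
  for (int c = 0; c < C; ++c) {
    const mat& sl = input.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const int r0 = i * stride, c0 = j * stride;
        double best = sl(r0, c0);
        int bi = r0, bj = c0;
        for (int dj = 0; dj < pool; ++dj)
          for (int di = 0; di < pool; ++di)
            if (sl(r0 + di, c0 + dj) > best) {
              best = sl(r0 + di, c0 + dj);
              bi = r0 + di; bj = c0 + dj;
            }
        out(i, j, c) = best;
        arg(i, j, c) = (uword)c * H * W + (uword)bj * H + bi;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("argmax") = arg);
}

// [[Rcpp::export]]
arma::cube maxpool_bwd(const arma::ucube& argmax, const arma::cube& gout,
                       int H, int W, int C) {
  cube dinput(H, W, C, fill::zeros);
  const uword n = argmax.n_elem;
  for (uword t = 0; t < n; ++t) dinput(argmax(t)) += gout(t);
  return dinput;
}
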