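// Low-level tensor ops for the encoder-decoder segmentation network.
// Layout: feature maps are arma::cube (rows = H, cols = W, slices = channels).
// Convolution weights are (k*k*Cin) x Cout matrices; the im2col column order
// is channel-major, then kernel column, then kernel row (see im2col below) and
// must stay consistent between the forward and backward passes.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// "same" padding: pad_before = (k-1)/2, pad_after = k-1-pad_before, stride 1.
// Out-of-range taps read zero.
static arma::mat im2col(const arma::cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pb = (k - 1) / 2;
  arma::mat P(H * W, k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& xc = x.slice(c);
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = c * k * k + dj * k + di;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - pb;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di - pb;
            if (si < 0 || si >= H) continue;
            P(j * H + i, col) = xc(si, sj);
          }
        }
      }
    }
  }
  return P;
}

// [[Rcpp::export(name = ".conv2d_fw")]]
arma::cube conv2d_fw(const arma::cube& x, const arma::mat& w,
                     const arma::vec& b, const int k) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_cols;
  arma::mat P = im2col(x, k);
  arma::mat Y = P * w;
  Y.each_row() += b.t();
  arma::cube y(H, W, Cout);
  for (int c = 0; c < Cout; ++c)
    y.slice(c) = arma::reshape(Y.col(c), H, W);
  return y;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(const arma::cube& x, const arma::mat& w,
               const arma::cube& gy, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Cout = w.n_cols;
  const int pb = (k - 1) / 2;

  arma::mat GY(H * W, Cout);
  for (int c = 0; c < Cout; ++c)
    GY.col(c) = arma::vectorise(gy.slice(c));

  arma::mat P = im2col(x, k);
  arma::mat gw = P.t() * GY;
  arma::vec gb = arma::sum(GY, 0).t();

  // col2im: scatter GY * w^T back onto the input grid
  arma::mat GP = GY * w.t();
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    arma::mat& gxc = gx.slice(c);
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = c * k * k + dj * k + di;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - pb;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di - pb;
            if (si < 0 || si >= H) continue;
            gxc(si, sj) += GP(j * H + i, col);
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2. Requires even H and W.
// [[Rcpp::export(name = ".maxpool2_fw")]]
List maxpool2_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int h = H / 2, w = W / 2;
  arma::cube y(h, w, C);
  arma::ucube idx(h, w, C);  // linear index into the input slice
  for (int c = 0; c < C; ++c) {
    const arma::mat& xc = x.slice(c);
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < h; ++i) {
        double best = xc(2 * i, 2 * j);
        int bi = 2 * i, bj = 2 * j;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const double v = xc(2 * i + di, 2 * j + dj);
            if (v > best) { best = v; bi = 2 * i + di; bj = 2 * j + dj; }
          }
        y(i, j, c) = best;
        idx(i, j, c) = (arma::uword)(bj * H + bi);
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bw")]]
arma::cube maxpool2_bw(const arma::cube& gy, const arma::ucube& idx,
                       const int H, const int W) {
  const int h = gy.n_rows, w = gy.n_cols, C = gy.n_slices;
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    arma::mat& gxc = gx.slice(c);
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i)
        gxc(idx(i, j, c)) += gy(i, j, c);
  }
  return gx;
}

// Nearest-neighbour x2 upsampling.
// [[Rcpp::export(name = ".upsample2_fw")]]
arma::cube upsample2_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v;
        y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v;
        y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

// [[Rcpp::export(name = ".upsample2_bw")]]
arma::cube upsample2_bw(const arma::cube& gy) {
  const int H = gy.n_rows / 2, W = gy.n_cols / 2, C = gy.n_slices;
  arma::cube gx(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        gx(i, j, c) = gy(2 * i, 2 * j, c) + gy(2 * i + 1, 2 * j, c) +
                      gy(2 * i, 2 * j + 1, c) + gy(2 * i + 1, 2 * j + 1, c);
  return gx;
}
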