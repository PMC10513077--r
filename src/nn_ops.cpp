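// Minimal conv-net primitives for the encoder-decoder segmenter.
// Feature maps are arma::cube (H, W, C); 3x3 convs use same-padding via
// im2col, so every layer preserves spatial shape.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col3(const cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat out(C * 9, (size_t)H * W, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    int k = 0;
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int row = c * 9 + k; ++k;
        for (int j = 0; j < W; ++j) {
          const int jj = j + dj;
          if (jj < 0 || jj >= W) continue;
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          for (int i = i0; i < i1; ++i)
            out(row, (size_t)j * H + i) = xc(i + di, jj);
        }
      }
    }
  }
  return out;
}

static cube col2im3(const mat& cols, int H, int W, int C) {
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& dxc = dx.slice(c);
    int k = 0;
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int row = c * 9 + k; ++k;
        for (int j = 0; j < W; ++j) {
          const int jj = j + dj;
          if (jj < 0 || jj >= W) continue;
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          for (int i = i0; i < i1; ++i)
            dxc(i + di, jj) += cols(row, (size_t)j * H + i);
        }
      }
    }
  }
  return dx;
}

// [[Rcpp::export]]
arma::cube nn_conv3_fw(const arma::cube& x, const arma::mat& w,
                       const arma::vec& b) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_rows;
  mat y = w * im2col3(x);
  y.each_col() += b;
  cube out(H, W, Cout);
  for (int o = 0; o < Cout; ++o)
    out.slice(o) = reshape(y.row(o), H, W);
  return out;
}

// [[Rcpp::export]]
Rcpp::List nn_conv3_bw(const arma::cube& x, const arma::mat& w,
                       const arma::cube& dy) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Cout = dy.n_slices;
  mat cols = im2col3(x);
  mat dym(Cout, (size_t)H * W);
  for (int o = 0; o < Cout; ++o)
    dym.row(o) = vectorise(dy.slice(o)).t();
  mat dw = dym * cols.t();
  vec db = sum(dym, 1);
  cube dx = col2im3(w.t() * dym, H, W, C);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// 2x2 max pooling; stores the flat within-slice argmax for the backward pass
// [[Rcpp::export]]
Rcpp::List nn_pool_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int H2 = H / 2, W2 = W / 2;
  cube y(H2, W2, C);
  umat idx((size_t)H2 * W2, C);
  for (int c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (int j = 0; j < W2; ++j) {
      for (int i = 0; i < H2; ++i) {
        double best = -datum::inf; uword bi = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const int ii = 2 * i + di, jj = 2 * j + dj;
            if (xc(ii, jj) > best) { best = xc(ii, jj); bi = (uword)jj * H + ii; }
          }
        y(i, j, c) = best;
        idx((size_t)j * H2 + i, c) = bi;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube nn_pool_bw(const arma::umat& idx, const arma::cube& dy,
                      int H, int W) {
  const int C = dy.n_slices;
  const int H2 = dy.n_rows, W2 = dy.n_cols;
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& dxc = dx.slice(c);
    const mat& dyc = dy.slice(c);
    for (int j = 0; j < W2; ++j)
      for (int i = 0; i < H2; ++i)
        dxc(idx((size_t)j * H2 + i, c)) += dyc(i, j);
  }
  return dx;
}

// nearest-neighbour 2x upsampling
// [[Rcpp::export]]
arma::cube nn_up_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v; y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v; y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

// [[Rcpp::export]]
arma::cube nn_up_bw(const arma::cube& dy) {
  const int H = dy.n_rows / 2, W = dy.n_cols / 2, C = dy.n_slices;
  cube dx(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        dx(i, j, c) = dy(2 * i, 2 * j, c) + dy(2 * i + 1, 2 * j, c) +
          dy(2 * i, 2 * j + 1, c) + dy(2 * i + 1, 2 * j + 1, c);
  return dx;
}
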