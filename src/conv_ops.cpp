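#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Feature maps are arma::cube (H rows, W cols, C slices), matching R arrays
// dim c(H, W, C).  Convolutions are stride-1 with "same" zero padding
// (pad = k/2).  Weight matrices are (k*k*Cin) x Cout with column layout
// col = c*k*k + dx*k + dy (dy = row offset, dx = col offset).

// [[Rcpp::export]]
arma::mat cpp_im2col(const arma::cube& x, const int k, const int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat out(H * W, k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy) {
        const int col = c * k * k + dx * k + dy;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dx - pad;
          if (sj < 0 || sj >= W) continue;
          double* o = out.colptr(col) + j * H;
          const double* s = x.slice_colptr(c, sj);
          const int i0 = std::max(0, pad - dy);
          const int i1 = std::min(H - 1, H - 1 + pad - dy);
          for (int i = i0; i <= i1; ++i) o[i] = s[i + dy - pad];
        }
      }
    }
  }
  return out;
}

// scatter-add inverse of cpp_im2col
static arma::cube col2im(const arma::mat& cols, const int H, const int W,
                         const int C, const int k, const int pad) {
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy) {
        const int col = c * k * k + dx * k + dy;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dx - pad;
          if (sj < 0 || sj >= W) continue;
          const double* g = cols.colptr(col) + j * H;
          double* s = x.slice_colptr(c, sj);
          const int i0 = std::max(0, pad - dy);
          const int i1 = std::min(H - 1, H - 1 + pad - dy);
          for (int i = i0; i <= i1; ++i) s[i + dy - pad] += g[i];
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(const arma::cube& x, const arma::mat& Wm,
                          const arma::vec& b, const int k) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = Wm.n_cols;
  const int pad = k / 2;
  arma::mat y = cpp_im2col(x, k, pad) * Wm;
  y.each_row() += b.t();
  return arma::cube(y.memptr(), H, W, Cout);
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(const arma::cube& x, const arma::mat& Wm,
                    const arma::cube& gy, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Cout = gy.n_slices;
  const int pad = k / 2;
  const arma::mat gym(const_cast<double*>(gy.memptr()), H * W, Cout, false);
  arma::mat xc = cpp_im2col(x, k, pad);
  arma::mat gW = xc.t() * gym;
  arma::vec gb = arma::sum(gym, 0).t();
  arma::mat gcol = gym * Wm.t();
  arma::cube gx = col2im(gcol, H, W, C, k, pad);
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// 2x2 max pooling, stride 2; H and W must be even.  idx stores 0..3
// (di + 2*dj) of the winning cell for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C), idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double best = x(2 * i, 2 * j, c);
        int bk = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const double v = x(2 * i + di, 2 * j + dj, c);
            if (v > best) { best = v; bk = di + 2 * dj; }
          }
        y(i, j, c) = best;
        idx(i, j, c) = bk;
      }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bwd(const arma::cube& idx, const arma::cube& gy,
                            const int H, const int W) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, C = gy.n_slices;
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const int bk = (int) idx(i, j, c);
        gx(2 * i + bk % 2, 2 * j + bk / 2, c) += gy(i, j, c);
      }
  return gx;
}

// bilinear x2 upsampling, half-pixel-center convention (corners not aligned)
static void up2_weights(const int Hi, const int Ho, arma::ivec& i0,
                        arma::ivec& i1, arma::vec& w) {
  i0.set_size(Ho); i1.set_size(Ho); w.set_size(Ho);
  for (int i = 0; i < Ho; ++i) {
    double s = (i + 0.5) / 2.0 - 0.5;
    int a = (int) std::floor(s);
    double t = s - a;
    int b = a + 1;
    if (a < 0) a = 0;
    if (b > Hi - 1) b = Hi - 1;
    i0(i) = a; i1(i) = b; w(i) = t;
  }
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = 2 * H, Wo = 2 * W;
  arma::ivec r0, r1, c0, c1;
  arma::vec wr, wc;
  up2_weights(H, Ho, r0, r1, wr);
  up2_weights(W, Wo, c0, c1, wc);
  arma::cube y(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        y(i, j, c) =
          (1 - wr(i)) * (1 - wc(j)) * x(r0(i), c0(j), c) +
          wr(i)       * (1 - wc(j)) * x(r1(i), c0(j), c) +
          (1 - wr(i)) * wc(j)       * x(r0(i), c1(j), c) +
          wr(i)       * wc(j)       * x(r1(i), c1(j), c);
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_bwd(const arma::cube& gy, const int H, const int W) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, C = gy.n_slices;
  arma::ivec r0, r1, c0, c1;
  arma::vec wr, wc;
  up2_weights(H, Ho, r0, r1, wr);
  up2_weights(W, Wo, c0, c1, wc);
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const double g = gy(i, j, c);
        gx(r0(i), c0(j), c) += (1 - wr(i)) * (1 - wc(j)) * g;
        gx(r1(i), c0(j), c) += wr(i)       * (1 - wc(j)) * g;
        gx(r0(i), c1(j), c) += (1 - wr(i)) * wc(j)       * g;
        gx(r1(i), c1(j), c) += wr(i)       * wc(j)       * g;
      }
  return gx;
}

// average pooling with kernel = stride = k on a single map; trailing
// rows/cols that do not fill a block are dropped (floor division)
// [[Rcpp::export]]
arma::mat cpp_avgpool(const arma::mat& x, const int k) {
  const int Ho = x.n_rows / k, Wo = x.n_cols / k;
  arma::mat y(Ho, Wo);
  for (int j = 0; j < Wo; ++j)
    for (int i = 0; i < Ho; ++i)
      y(i, j) = arma::accu(x.submat(i * k, j * k, i * k + k - 1,
                                    j * k + k - 1)) / (k * k);
  return y;
}

// [[Rcpp::export]]
arma::mat cpp_avgpool_bwd(const arma::mat& gy, const int k, const int H,
                          const int W) {
  const int Ho = gy.n_rows, Wo = gy.n_cols;
  arma::mat gx(H, W, arma::fill::zeros);
  for (int j = 0; j < Wo; ++j)
    for (int i = 0; i < Ho; ++i)
      gx.submat(i * k, j * k, i * k + k - 1, j * k + k - 1)
        .fill(gy(i, j) / (k * k));
  return gx;
}
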