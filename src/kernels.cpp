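// Low-level numeric kernels: im2col/col2im convolution support, 2x2 max
// pooling, bilinear resampling, and seed-connected components.
// Layout convention everywhere: arrays are (height, width, channel),
// column-major as R stores them; im2col flattens each receptive field
// patch in column-major (row, col, channel) order so that
// as.vector(W[,,c,o]) lines up with patch features.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// x: cube (H, W, C). Returns (k*k*C) x (H_out*W_out) matrix of patches,
// zero padded by `pad`, stride 1.
// [[Rcpp::export]]
arma::mat cpp_im2col(const arma::cube& x, const int k, const int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H + 2 * pad - k + 1;
  const int Wo = W + 2 * pad - k + 1;
  if (Ho < 1 || Wo < 1) stop("kernel larger than padded input");
  arma::mat out(k * k * C, Ho * Wo, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < k; ++j) {       // kernel col offset
      for (int i = 0; i < k; ++i) {     // kernel row offset
        const int frow = c * k * k + j * k + i;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo + j - pad;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho + i - pad;
            if (hi < 0 || hi >= H) continue;
            out(frow, wo * Ho + ho) = x(hi, wi, c);
          }
        }
      }
    }
  }
  return out;
}

// Scatter-add inverse of cpp_im2col: cols is (k*k*C) x (Ho*Wo).
// [[Rcpp::export]]
arma::cube cpp_col2im(const arma::mat& cols, const int H, const int W,
                      const int C, const int k, const int pad) {
  const int Ho = H + 2 * pad - k + 1;
  const int Wo = W + 2 * pad - k + 1;
  arma::cube out(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < k; ++j) {
      for (int i = 0; i < k; ++i) {
        const int frow = c * k * k + j * k + i;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo + j - pad;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho + i - pad;
            if (hi < 0 || hi >= H) continue;
            out(hi, wi, c) += cols(frow, wo * Ho + ho);
          }
        }
      }
    }
  }
  return out;
}

// 2x2 max pool, stride 2; odd trailing row/col dropped. Returns pooled cube
// and 1-based linear argmax indices into the input cube (ties -> first in
// column-major scan order, so results are deterministic).
// [[Rcpp::export]]
List cpp_maxpool2(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube out(Ho, Wo, C);
  arma::ucube idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double best = -arma::datum::inf;
        arma::uword bi = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const int hi = 2 * ho + di, wi = 2 * wo + dj;
            const double v = x(hi, wi, c);
            if (v > best) {
              best = v;
              bi = (arma::uword)c * H * W + (arma::uword)wi * H + hi;
            }
          }
        }
        out(ho, wo, c) = best;
        idx(ho, wo, c) = bi + 1;  // 1-based for R
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = idx);
}

// Bilinear resize of a single-channel matrix using half-pixel-center
// alignment (the convention of common image libraries): the source
// coordinate of destination pixel d is (d + 0.5) * scale - 0.5, clamped.
// [[Rcpp::export]]
arma::mat cpp_bilinear_resize(const arma::mat& x, const int oh, const int ow) {
  const int H = x.n_rows, W = x.n_cols;
  if (oh < 1 || ow < 1) stop("output size must be positive");
  arma::mat out(oh, ow);
  const double sr = (double)H / oh, sc = (double)W / ow;
  for (int j = 0; j < ow; ++j) {
    double fc = (j + 0.5) * sc - 0.5;
    if (fc < 0) fc = 0;
    if (fc > W - 1) fc = W - 1;
    const int c0 = (int)std::floor(fc);
    const int c1 = std::min(c0 + 1, W - 1);
    const double wc = fc - c0;
    for (int i = 0; i < oh; ++i) {
      double fr = (i + 0.5) * sr - 0.5;
      if (fr < 0) fr = 0;
      if (fr > H - 1) fr = H - 1;
      const int r0 = (int)std::floor(fr);
      const int r1 = std::min(r0 + 1, H - 1);
      const double wr = fr - r0;
      out(i, j) = (1 - wr) * ((1 - wc) * x(r0, c0) + wc * x(r0, c1)) +
                  wr * ((1 - wc) * x(r1, c0) + wc * x(r1, c1));
    }
  }
  return out;
}

// 8-connected component of `mask` containing seed (r, c) (0-based).
// Plain BFS; returns a logical matrix.
// [[Rcpp::export]]
LogicalMatrix cpp_component_at(const LogicalMatrix& mask, const int r,
                               const int c) {
  const int H = mask.nrow(), W = mask.ncol();
  if (r < 0 || r >= H || c < 0 || c >= W) stop("seed outside image");
  LogicalMatrix comp(H, W);
  if (!mask(r, c)) return comp;
  std::vector<int> stack;
  stack.push_back(c * H + r);
  comp(r, c) = true;
  while (!stack.empty()) {
    const int cur = stack.back();
    stack.pop_back();
    const int cr = cur % H, cc = cur / H;
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0) continue;
        const int nr = cr + di, nc = cc + dj;
        if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
        if (mask(nr, nc) && !comp(nr, nc)) {
          comp(nr, nc) = true;
          stack.push_back(nc * H + nr);
        }
      }
    }
  }
  return comp;
}
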