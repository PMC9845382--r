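// Low-level tensor ops for the skin-segmentation U-Net.
// Activations are arma::cube with layout (depth rows x lateral cols x channels);
// conv weights are (C_out x C_in*9) matrices in im2col order, up-conv weights are
// (C_out x C_in*4) block matrices [W00 W10 W01 W11] for the 2x2 stride-2 kernel.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;
using arma::uword;

// Unpack 3x3 same-padded neighborhoods in pixel-major layout: row index
// i + j*H for output pixel (i, j), column index c*9 + (dj+1)*3 + (di+1).
// Writes run down contiguous columns, which keeps this memory-bound step
// cache friendly.
static mat im2col3(const cube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat out(H * W, C * 9, arma::fill::zeros);
  for (uword c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    const uword r0 = c * 9;
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const uword r = r0 + (uword)((dj + 1) * 3 + (di + 1));
        double* dst = out.colptr(r);
        for (uword j = 0; j < W; ++j) {
          const int js = (int)j + dj;
          if (js < 0 || js >= (int)W) continue;
          const uword i_lo = (di < 0) ? 1u : 0u;
          const uword i_hi = (di > 0) ? H - 1 : H;
          const double* src = xs.colptr((uword)js);
          for (uword i = i_lo; i < i_hi; ++i)
            dst[i + j * H] = src[i + di];
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col3: scatter-add the pixel-major columns back into an
// H x W x C cube.
static cube col2im3(const mat& cols, uword H, uword W, uword C) {
  cube x(H, W, C, arma::fill::zeros);
  for (uword c = 0; c < C; ++c) {
    mat& xs = x.slice(c);
    const uword r0 = c * 9;
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const uword r = r0 + (uword)((dj + 1) * 3 + (di + 1));
        const double* src = cols.colptr(r);
        for (uword j = 0; j < W; ++j) {
          const int js = (int)j + dj;
          if (js < 0 || js >= (int)W) continue;
          const uword i_lo = (di < 0) ? 1u : 0u;
          const uword i_hi = (di > 0) ? H - 1 : H;
          double* dst = xs.colptr((uword)js);
          for (uword i = i_lo; i < i_hi; ++i)
            dst[i + di] += src[i + j * H];
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
arma::cube cpp_conv3_fw(const arma::cube& x, const arma::mat& w, const arma::vec& b,
                        bool relu = false) {
  const uword H = x.n_rows, W = x.n_cols;
  const uword Cout = w.n_rows;
  mat cols = im2col3(x);    // (H*W) x (C*9)
  mat yt = cols * w.t();    // (H*W) x Cout, matches cube memory layout
  cube y(yt.memptr(), H, W, Cout);
  for (uword o = 0; o < Cout; ++o) y.slice(o) += b(o);
  if (relu) y.transform([](double v) { return v > 0 ? v : 0.0; });
  return y;
}

// [[Rcpp::export]]
List cpp_conv3_bw(const arma::cube& x, const arma::mat& w, const arma::cube& dy) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const uword Cout = dy.n_slices;
  mat cols = im2col3(x);           // (H*W) x (C*9)
  mat dym(const_cast<double*>(dy.memptr()), H * W, Cout, false, true);
  mat dw = dym.t() * cols;         // Cout x C*9
  vec db = arma::sum(dym, 0).t();  // Cout
  mat dcols = dym * w;             // (H*W) x (C*9)
  cube dx = col2im3(dcols, H, W, C);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 stride-2 max pooling; idx records the winning linear index within each slice.
// [[Rcpp::export]]
List cpp_maxpool_fw(const arma::cube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const uword Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  arma::ucube idx(Ho, Wo, C);
  for (uword c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (uword j = 0; j < Wo; ++j) {
      for (uword i = 0; i < Ho; ++i) {
        uword best = 2 * i + (2 * j) * H;
        double bv = xs(2 * i, 2 * j);
        const uword cand[3] = {2 * i + 1 + (2 * j) * H,
                               2 * i + (2 * j + 1) * H,
                               2 * i + 1 + (2 * j + 1) * H};
        for (int k = 0; k < 3; ++k) {
          double v = xs(cand[k] % H, cand[k] / H);
          if (v > bv) { bv = v; best = cand[k]; }
        }
        y(i, j, c) = bv;
        idx(i, j, c) = best;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_bw(const arma::cube& dy, const arma::ucube& idx,
                          int H, int W) {
  const uword C = dy.n_slices;
  cube dx((uword)H, (uword)W, C, arma::fill::zeros);
  for (uword c = 0; c < C; ++c) {
    mat& dxs = dx.slice(c);
    const mat& dys = dy.slice(c);
    const arma::umat& is = idx.slice(c);
    for (uword j = 0; j < dy.n_cols; ++j)
      for (uword i = 0; i < dy.n_rows; ++i)
        dxs(is(i, j) % (uword)H, is(i, j) / (uword)H) += dys(i, j);
  }
  return dx;
}

// Transposed 2x2 stride-2 convolution: out(2i+di, 2j+dj, :) += W[di,dj] x(i, j, :).
// [[Rcpp::export]]
arma::cube cpp_upconv_fw(const arma::cube& x, const arma::mat& w, const arma::vec& b,
                         bool relu = false) {
  const uword H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const uword Cout = w.n_rows;
  mat xm(const_cast<double*>(x.memptr()), H * W, Cin, false, true);
  cube y(2 * H, 2 * W, Cout);
  for (uword o = 0; o < Cout; ++o) y.slice(o).fill(b(o));
  for (uword dj = 0; dj < 2; ++dj) {
    for (uword di = 0; di < 2; ++di) {
      const uword k = dj * 2 + di;
      mat yk = xm * w.cols(k * Cin, (k + 1) * Cin - 1).t(); // H*W x Cout
      for (uword o = 0; o < Cout; ++o) {
        mat& ys = y.slice(o);
        const double* src = yk.colptr(o);
        for (uword j = 0; j < W; ++j)
          for (uword i = 0; i < H; ++i)
            ys(2 * i + di, 2 * j + dj) += src[i + j * H];
      }
    }
  }
  if (relu) y.transform([](double v) { return v > 0 ? v : 0.0; });
  return y;
}

// [[Rcpp::export]]
List cpp_upconv_bw(const arma::cube& x, const arma::mat& w, const arma::cube& dy) {
  const uword H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const uword Cout = dy.n_slices;
  mat xm(const_cast<double*>(x.memptr()), H * W, Cin, false, true);
  mat dw(Cout, Cin * 4, arma::fill::zeros);
  mat dxm(H * W, Cin, arma::fill::zeros);
  vec db(Cout, arma::fill::zeros);
  for (uword o = 0; o < Cout; ++o) db(o) = arma::accu(dy.slice(o));
  mat dyk(H * W, Cout);
  for (uword dj = 0; dj < 2; ++dj) {
    for (uword di = 0; di < 2; ++di) {
      const uword k = dj * 2 + di;
      for (uword o = 0; o < Cout; ++o) {
        const mat& dys = dy.slice(o);
        double* dst = dyk.colptr(o);
        for (uword j = 0; j < W; ++j)
          for (uword i = 0; i < H; ++i)
            dst[i + j * H] = dys(2 * i + di, 2 * j + dj);
      }
      dw.cols(k * Cin, (k + 1) * Cin - 1) = dyk.t() * xm;
      dxm += dyk * w.cols(k * Cin, (k + 1) * Cin - 1);
    }
  }
  cube dx(dxm.memptr(), H, W, Cin);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
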