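// Low-level tensor kernels for the network layers.
// Feature maps are R arrays [H, W, C] (column-major), mapped onto arma::cube
// with n_rows = H, n_cols = W, n_slices = C. Convolution weights are R arrays
// [kh, kw, C_in, C_out]. All convolutions are cross-correlations (the deep
// learning convention).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col(const arma::cube& x, int kh, int kw,
                        int sh, int sw, int ph, int pw,
                        int Hout, int Wout) {
  const int Cin = x.n_slices;
  arma::mat col(kh * kw * Cin, (size_t)Hout * Wout, arma::fill::zeros);
  const int H = x.n_rows, W = x.n_cols;
  for (int oj = 0; oj < Wout; ++oj) {
    for (int oi = 0; oi < Hout; ++oi) {
      const size_t p = (size_t)oi + (size_t)Hout * oj;
      double* colp = col.colptr(p);
      for (int c = 0; c < Cin; ++c) {
        for (int b = 0; b < kw; ++b) {
          const int jj = oj * sw - pw + b;
          if (jj < 0 || jj >= W) continue;
          for (int a = 0; a < kh; ++a) {
            const int ii = oi * sh - ph + a;
            if (ii < 0 || ii >= H) continue;
            colp[a + kh * (b + kw * c)] = x(ii, jj, c);
          }
        }
      }
    }
  }
  return col;
}

static void col2im_add(arma::cube& dx, const arma::mat& dcol, int kh, int kw,
                       int sh, int sw, int ph, int pw, int Hout, int Wout) {
  const int Cin = dx.n_slices, H = dx.n_rows, W = dx.n_cols;
  for (int oj = 0; oj < Wout; ++oj) {
    for (int oi = 0; oi < Hout; ++oi) {
      const size_t p = (size_t)oi + (size_t)Hout * oj;
      const double* colp = dcol.colptr(p);
      for (int c = 0; c < Cin; ++c) {
        for (int b = 0; b < kw; ++b) {
          const int jj = oj * sw - pw + b;
          if (jj < 0 || jj >= W) continue;
          for (int a = 0; a < kh; ++a) {
            const int ii = oi * sh - ph + a;
            if (ii < 0 || ii >= H) continue;
            dx(ii, jj, c) += colp[a + kh * (b + kw * c)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::vec& w,
                      const arma::vec& b, int kh, int kw, int cout,
                      int sh, int sw, int ph, int pw) {
  const int Cin = x.n_slices;
  const int Hout = (int)((x.n_rows + 2 * ph - kh) / sh) + 1;
  const int Wout = (int)((x.n_cols + 2 * pw - kw) / sw) + 1;
  arma::mat W(const_cast<double*>(w.memptr()), kh * kw * Cin, cout, false, true);
  arma::mat col = im2col(x, kh, kw, sh, sw, ph, pw, Hout, Wout);
  arma::mat out = W.t() * col;              // cout x (Hout*Wout)
  out.each_col() += b;
  arma::cube y(Hout, Wout, cout);
  for (int c = 0; c < cout; ++c)
    y.slice(c) = arma::reshape(out.row(c).t(), Hout, Wout);
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(const arma::cube& x, const arma::vec& w, const arma::cube& dout,
                int kh, int kw, int sh, int sw, int ph, int pw) {
  const int Cin = x.n_slices;
  const int cout = dout.n_slices;
  const int Hout = dout.n_rows, Wout = dout.n_cols;
  arma::mat W(const_cast<double*>(w.memptr()), kh * kw * Cin, cout, false, true);
  arma::mat doutm(cout, (size_t)Hout * Wout);
  for (int c = 0; c < cout; ++c)
    doutm.row(c) = arma::vectorise(dout.slice(c)).t();
  arma::mat col = im2col(x, kh, kw, sh, sw, ph, pw, Hout, Wout);
  arma::mat dW = col * doutm.t();           // (kh*kw*Cin) x cout
  arma::vec db = arma::sum(doutm, 1);
  arma::mat dcol = W * doutm;               // (kh*kw*Cin) x P
  arma::cube dx(x.n_rows, x.n_cols, Cin, arma::fill::zeros);
  col2im_add(dx, dcol, kh, kw, sh, sw, ph, pw, Hout, Wout);
  return List::create(_["dx"] = dx, _["dw"] = arma::vec(arma::vectorise(dW)),
                      _["db"] = db);
}

// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd(const arma::cube& x, int k, int s, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Hout = (H + 2 * pad - k) / s + 1;
  const int Wout = (W + 2 * pad - k) / s + 1;
  arma::cube y(Hout, Wout, C);
  arma::ucube idx(Hout, Wout, C);           // linear index into input slice
  for (int c = 0; c < C; ++c) {
    for (int oj = 0; oj < Wout; ++oj) {
      for (int oi = 0; oi < Hout; ++oi) {
        double best = -arma::datum::inf; size_t bi = 0;
        for (int b = 0; b < k; ++b) {
          const int jj = oj * s - pad + b;
          if (jj < 0 || jj >= W) continue;
          for (int a = 0; a < k; ++a) {
            const int ii = oi * s - pad + a;
            if (ii < 0 || ii >= H) continue;
            const double v = x(ii, jj, c);
            if (v > best) { best = v; bi = (size_t)ii + (size_t)H * jj; }
          }
        }
        y(oi, oj, c) = best;
        idx(oi, oj, c) = bi;
      }
    }
  }
  return List::create(_["out"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
arma::cube maxpool_bwd(const arma::ucube& idx, const arma::cube& dout,
                       int H, int W) {
  const int C = dout.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* sl = dx.slice_memptr(c);
    for (size_t q = 0; q < dout.n_rows * dout.n_cols; ++q)
      sl[idx.slice(c)(q)] += dout.slice(c)(q);
  }
  return dx;
}

// [[Rcpp::export(name = ".avgpool_fwd")]]
arma::cube avgpool_fwd(const arma::cube& x, int k, int s) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Hout = (H - k) / s + 1, Wout = (W - k) / s + 1;
  arma::cube y(Hout, Wout, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int oj = 0; oj < Wout; ++oj)
      for (int oi = 0; oi < Hout; ++oi) {
        double acc = 0;
        for (int b = 0; b < k; ++b)
          for (int a = 0; a < k; ++a)
            acc += x(oi * s + a, oj * s + b, c);
        y(oi, oj, c) = acc / (k * k);
      }
  return y;
}

// [[Rcpp::export(name = ".avgpool_bwd")]]
arma::cube avgpool_bwd(const arma::cube& dout, int k, int s, int H, int W) {
  const int C = dout.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  const double f = 1.0 / (k * k);
  for (int c = 0; c < C; ++c)
    for (size_t oj = 0; oj < dout.n_cols; ++oj)
      for (size_t oi = 0; oi < dout.n_rows; ++oi) {
        const double g = dout(oi, oj, c) * f;
        for (int b = 0; b < k; ++b)
          for (int a = 0; a < k; ++a)
            dx(oi * s + a, oj * s + b, c) += g;
      }
  return dx;
}

// Edge-preserving bilateral filter on a [H, W] grayscale image in [0, 1].
// d: window diameter (odd); sigma_color in intensity units, sigma_space in px.
// [[Rcpp::export(name = ".bilateral_filter")]]
arma::mat bilateral_filter(const arma::mat& x, int d, double sigma_color,
                           double sigma_space) {
  const int H = x.n_rows, W = x.n_cols, r = d / 2;
  arma::mat y(H, W);
  arma::mat sw(d, d);
  for (int b = -r; b <= r; ++b)
    for (int a = -r; a <= r; ++a)
      sw(a + r, b + r) = std::exp(-(a * a + b * b) / (2.0 * sigma_space * sigma_space));
  const double cc = 2.0 * sigma_color * sigma_color;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const double v0 = x(i, j);
      double num = 0, den = 0;
      for (int b = -r; b <= r; ++b) {
        const int jj = j + b;
        if (jj < 0 || jj >= W) continue;
        for (int a = -r; a <= r; ++a) {
          const int ii = i + a;
          if (ii < 0 || ii >= H) continue;
          const double v = x(ii, jj);
          const double dv = v - v0;
          const double wgt = sw(a + r, b + r) * std::exp(-dv * dv / cc);
          num += wgt * v; den += wgt;
        }
      }
      y(i, j) = num / den;
    }
  return y;
}
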