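// 3D convolution kernels (im2col + GEMM) backing the autodiff tape.
// Tensor layout everywhere: R array dim = c(H, W, T, C, N), column-major,
// so the (H, W, T) block of one (channel, sample) slab is contiguous.
// Weight layout: dim = c(kh, kw, kt, Cin, Cout).
//
// The col matrix is stored transposed (M x K, M = Ho*Wo*To output voxels,
// K = kh*kw*kt*Cin): each K-column is contiguous over output voxels, so
// filling it walks contiguous input runs when the row stride is 1, and the
// GEMM result (M x Cout) maps straight onto the output memory layout.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int s, int p) {
  return (in + 2 * p - k) / s + 1;
}

// Fill the transposed im2col matrix (M x K) for one sample.
static void im2col_t(const double* x, int H, int W, int T, int C,
                     int kh, int kw, int kt, int sh, int sw, int st,
                     int ph, int pw, int pt, int Ho, int Wo, int To,
                     arma::mat& col) {
  const long HW = (long)H * W, HWT = HW * T;
  int r = 0;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (long)c * HWT;
    for (int dt = 0; dt < kt; ++dt) {
      for (int dw = 0; dw < kw; ++dw) {
        for (int dh = 0; dh < kh; ++dh, ++r) {
          double* cr = col.colptr(r);
          long m = 0;
          for (int to = 0; to < To; ++to) {
            const int t = to * st - pt + dt;
            if (t < 0 || t >= T) {
              std::fill(cr + m, cr + m + (long)Wo * Ho, 0.0);
              m += (long)Wo * Ho;
              continue;
            }
            for (int wo = 0; wo < Wo; ++wo) {
              const int w = wo * sw - pw + dw;
              if (w < 0 || w >= W) {
                std::fill(cr + m, cr + m + Ho, 0.0);
                m += Ho;
                continue;
              }
              const double* src = xc + HW * t + (long)H * w;
              if (sh == 1) {
                // contiguous run over ho: h = ho - ph + dh
                int h0 = -ph + dh;             // h at ho = 0
                int lo = std::max(0, -h0);     // first valid ho
                int hi = std::min(Ho, H - h0); // one past last valid ho
                if (lo > 0) std::fill(cr + m, cr + m + lo, 0.0);
                if (hi > lo)
                  std::copy(src + h0 + lo, src + h0 + hi, cr + m + lo);
                if (hi < Ho) std::fill(cr + m + std::max(hi, lo), cr + m + Ho, 0.0);
                m += Ho;
              } else {
                for (int ho = 0; ho < Ho; ++ho, ++m) {
                  const int h = ho * sh - ph + dh;
                  cr[m] = (h >= 0 && h < H) ? src[h] : 0.0;
                }
              }
            }
          }
        }
      }
    }
  }
}

// Scatter-add of an (M x K) col-matrix gradient back to the input grad.
static void col2im_t(const arma::mat& col, double* gx, int H, int W, int T,
                     int C, int kh, int kw, int kt, int sh, int sw, int st,
                     int ph, int pw, int pt, int Ho, int Wo, int To) {
  const long HW = (long)H * W, HWT = HW * T;
  int r = 0;
  for (int c = 0; c < C; ++c) {
    double* gc = gx + (long)c * HWT;
    for (int dt = 0; dt < kt; ++dt) {
      for (int dw = 0; dw < kw; ++dw) {
        for (int dh = 0; dh < kh; ++dh, ++r) {
          const double* cr = col.colptr(r);
          long m = 0;
          for (int to = 0; to < To; ++to) {
            const int t = to * st - pt + dt;
            if (t < 0 || t >= T) { m += (long)Wo * Ho; continue; }
            for (int wo = 0; wo < Wo; ++wo) {
              const int w = wo * sw - pw + dw;
              if (w < 0 || w >= W) { m += Ho; continue; }
              double* dst = gc + HW * t + (long)H * w;
              if (sh == 1) {
                int h0 = -ph + dh;
                int lo = std::max(0, -h0);
                int hi = std::min(Ho, H - h0);
                for (int ho = lo; ho < hi; ++ho) dst[h0 + ho] += cr[m + ho];
                m += Ho;
              } else {
                for (int ho = 0; ho < Ho; ++ho, ++m) {
                  const int h = ho * sh - ph + dh;
                  if (h >= 0 && h < H) dst[h] += cr[m];
                }
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv3d_fwd_cpp(NumericVector x, NumericVector w,
                             NumericVector bias, IntegerVector stride,
                             IntegerVector pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], T = xd[2], C = xd[3], N = xd[4];
  const int kh = wd[0], kw = wd[1], kt = wd[2], Co = wd[4];
  if (wd[3] != C) stop("channel mismatch between input and filter");
  const int sh = stride[0], sw = stride[1], st = stride[2];
  const int ph = pad[0], pw = pad[1], pt = pad[2];
  const int Ho = out_size(H, kh, sh, ph), Wo = out_size(W, kw, sw, pw),
            To = out_size(T, kt, st, pt);
  const long K = (long)kh * kw * kt * C, M = (long)Ho * Wo * To;

  NumericVector out((long)M * Co * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, To, Co, N);
  arma::mat wmat(const_cast<double*>(w.begin()), K, Co, false, true);
  const bool is1x1 = (kh == 1 && kw == 1 && kt == 1 && sh == 1 && sw == 1 &&
                      st == 1 && ph == 0 && pw == 0 && pt == 0);
  arma::mat col;
  if (!is1x1) col.set_size(M, K);
  for (int n = 0; n < N; ++n) {
    arma::mat omat(out.begin() + (long)n * M * Co, M, Co, false, true);
    if (is1x1) {
      arma::mat xmat(const_cast<double*>(x.begin()) + (long)n * M * C,
                     M, C, false, true);
      omat = xmat * wmat;  // wmat is (C x Co) here
    } else {
      im2col_t(x.begin() + (long)n * H * W * T * C, H, W, T, C, kh, kw, kt,
               sh, sw, st, ph, pw, pt, Ho, Wo, To, col);
      omat = col * wmat;
    }
    if (bias.size())
      for (int c = 0; c < Co; ++c) omat.col(c) += bias[c];
  }
  return out;
}

// Gradient w.r.t. the convolution input; also the forward pass of the
// transposed convolution (gout plays the role of its input).
// [[Rcpp::export]]
NumericVector conv3d_bw_input_cpp(NumericVector gout, NumericVector w,
                                  IntegerVector in_dim, IntegerVector stride,
                                  IntegerVector pad) {
  IntegerVector gd = gout.attr("dim"), wd = w.attr("dim");
  const int Ho = gd[0], Wo = gd[1], To = gd[2], Co = gd[3], N = gd[4];
  const int kh = wd[0], kw = wd[1], kt = wd[2], C = wd[3];
  const int H = in_dim[0], W = in_dim[1], T = in_dim[2];
  const int sh = stride[0], sw = stride[1], st = stride[2];
  const int ph = pad[0], pw = pad[1], pt = pad[2];
  const long K = (long)kh * kw * kt * C, M = (long)Ho * Wo * To;

  NumericVector gx((long)H * W * T * C * N);  // zero-initialised
  gx.attr("dim") = IntegerVector::create(H, W, T, C, N);
  arma::mat wmat(const_cast<double*>(w.begin()), K, Co, false, true);
  const bool is1x1 = (kh == 1 && kw == 1 && kt == 1 && sh == 1 && sw == 1 &&
                      st == 1 && ph == 0 && pw == 0 && pt == 0);
  for (int n = 0; n < N; ++n) {
    arma::mat gmat(const_cast<double*>(gout.begin()) + (long)n * M * Co,
                   M, Co, false, true);
    if (is1x1) {
      arma::mat gxmat(gx.begin() + (long)n * M * C, M, C, false, true);
      gxmat = gmat * wmat.t();
    } else {
      arma::mat colg = gmat * wmat.t();  // M x K
      col2im_t(colg, gx.begin() + (long)n * H * W * T * C, H, W, T, C,
               kh, kw, kt, sh, sw, st, ph, pw, pt, Ho, Wo, To);
    }
  }
  return gx;
}

// Gradient w.r.t. the filter.
// [[Rcpp::export]]
NumericVector conv3d_bw_filter_cpp(NumericVector x, NumericVector gout,
                                   IntegerVector kdim, IntegerVector stride,
                                   IntegerVector pad) {
  IntegerVector xd = x.attr("dim"), gd = gout.attr("dim");
  const int H = xd[0], W = xd[1], T = xd[2], C = xd[3], N = xd[4];
  const int Ho = gd[0], Wo = gd[1], To = gd[2], Co = gd[3];
  const int kh = kdim[0], kw = kdim[1], kt = kdim[2];
  const int sh = stride[0], sw = stride[1], st = stride[2];
  const int ph = pad[0], pw = pad[1], pt = pad[2];
  const long K = (long)kh * kw * kt * C, M = (long)Ho * Wo * To;

  arma::mat gw(K, Co, arma::fill::zeros);
  const bool is1x1 = (kh == 1 && kw == 1 && kt == 1 && sh == 1 && sw == 1 &&
                      st == 1 && ph == 0 && pw == 0 && pt == 0);
  arma::mat col;
  if (!is1x1) col.set_size(M, K);
  for (int n = 0; n < N; ++n) {
    arma::mat gmat(const_cast<double*>(gout.begin()) + (long)n * M * Co,
                   M, Co, false, true);
    if (is1x1) {
      arma::mat xmat(const_cast<double*>(x.begin()) + (long)n * M * C,
                     M, C, false, true);
      gw += xmat.t() * gmat;
    } else {
      im2col_t(x.begin() + (long)n * H * W * T * C, H, W, T, C, kh, kw, kt,
               sh, sw, st, ph, pw, pt, Ho, Wo, To, col);
      gw += col.t() * gmat;
    }
  }
  NumericVector out(K * Co);
  std::copy(gw.begin(), gw.end(), out.begin());
  out.attr("dim") = IntegerVector::create(kh, kw, kt, C, Co);
  return out;
}

// Max pooling with kernel == stride (used with kernel 1x2x2).
// Returns the pooled tensor and 1-based argmax indices into x.
// [[Rcpp::export]]
List maxpool3d_fwd_cpp(NumericVector x, IntegerVector kernel) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], T = xd[2], C = xd[3], N = xd[4];
  const int kh = kernel[0], kw = kernel[1], kt = kernel[2];
  const int Ho = H / kh, Wo = W / kw, To = T / kt;
  const long HW = (long)H * W, HWT = HW * T;
  NumericVector out((long)Ho * Wo * To * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, To, C, N);
  IntegerVector amax(out.size());
  long o = 0;
  for (long cn = 0; cn < (long)C * N; ++cn) {
    const double* xs = x.begin() + cn * HWT;
    for (int to = 0; to < To; ++to)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho, ++o) {
          double best = R_NegInf; long bidx = 0;
          for (int dt = 0; dt < kt; ++dt)
            for (int dw = 0; dw < kw; ++dw)
              for (int dh = 0; dh < kh; ++dh) {
                const long idx = (ho * kh + dh) + H * (wo * kw + dw) +
                                 HW * (to * kt + dt);
                if (xs[idx] > best) { best = xs[idx]; bidx = idx; }
              }
          out[o] = best;
          amax[o] = (int)(cn * HWT + bidx + 1);
        }
  }
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector maxpool3d_bw_cpp(NumericVector gout, IntegerVector argmax,
                               IntegerVector in_dim) {
  long n = 1;
  for (int i = 0; i < in_dim.size(); ++i) n *= in_dim[i];
  NumericVector gx(n);
  gx.attr("dim") = in_dim;
  for (long i = 0; i < (long)gout.size(); ++i)
    gx[argmax[i] - 1] += gout[i];
  return gx;
}
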