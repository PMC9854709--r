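// Low-level neural-network primitives for the de-aliasing networks.
// All tensors use R's column-major array layout [H, W, C, N] (height, width,
// channels, batch); convolution weights are [KH, KW, Cin, Cout].
// Convolutions are computed per sample via an im2col buffer laid out as
// (Ho*Wo) x (KH*KW*Cin) so both the forward product and the data gradient
// are single BLAS gemms.

#include <RcppArmadillo.h>
#include <cstring>
using namespace Rcpp;

// [[Rcpp::depends(RcppArmadillo)]]

static NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector y((R_xlen_t)a * b * c * d);
  y.attr("dim") = IntegerVector::create(a, b, c, d);
  return y;
}

static IntegerVector alloc4i(int a, int b, int c, int d) {
  IntegerVector y((R_xlen_t)a * b * c * d);
  y.attr("dim") = IntegerVector::create(a, b, c, d);
  return y;
}

static void get_dims4(const NumericVector& x, int d[4]) {
  IntegerVector dim = x.attr("dim");
  if (dim.size() != 4) stop("expected a 4-d array");
  for (int i = 0; i < 4; ++i) d[i] = dim[i];
}

// colT: (Ho*Wo) x (KH*KW*C); row q = ho + Ho*wo, col r = kh + KH*(kw + KW*ci)
static void im2col(const double* x, int H, int W, int C,
                   int KH, int KW, int pad, int stride,
                   int Ho, int Wo, arma::mat& colT) {
  for (int ci = 0; ci < C; ++ci) {
    const double* xc = x + (std::size_t)ci * H * W;
    for (int kw = 0; kw < KW; ++kw) {
      for (int kh = 0; kh < KH; ++kh) {
        int r = kh + KH * (kw + KW * ci);
        double* dst = colT.colptr(r);
        for (int wo = 0; wo < Wo; ++wo) {
          int in_j = wo * stride + kw - pad;
          double* dcol = dst + (std::size_t)wo * Ho;
          if (in_j < 0 || in_j >= W) {
            std::fill(dcol, dcol + Ho, 0.0);
            continue;
          }
          const double* src = xc + (std::size_t)in_j * H;
          if (stride == 1) {
            // contiguous copy of the valid row range, zeros at the borders
            int lo = std::max(0, pad - kh);          // ho range start
            int hi = std::min(Ho, H + pad - kh);     // ho range end (excl)
            if (lo > 0) std::fill(dcol, dcol + lo, 0.0);
            if (hi > lo)
              std::memcpy(dcol + lo, src + lo + kh - pad,
                          (std::size_t)(hi - lo) * sizeof(double));
            if (hi < Ho) std::fill(dcol + hi, dcol + Ho, 0.0);
          } else {
            for (int ho = 0; ho < Ho; ++ho) {
              int in_i = ho * stride + kh - pad;
              dcol[ho] = (in_i >= 0 && in_i < H) ? src[in_i] : 0.0;
            }
          }
        }
      }
    }
  }
}

static void col2im_acc(const arma::mat& colT, double* dx, int H, int W, int C,
                       int KH, int KW, int pad, int stride, int Ho, int Wo) {
  for (int ci = 0; ci < C; ++ci) {
    double* xc = dx + (std::size_t)ci * H * W;
    for (int kw = 0; kw < KW; ++kw) {
      for (int kh = 0; kh < KH; ++kh) {
        int r = kh + KH * (kw + KW * ci);
        const double* src0 = colT.colptr(r);
        for (int wo = 0; wo < Wo; ++wo) {
          int in_j = wo * stride + kw - pad;
          if (in_j < 0 || in_j >= W) continue;
          const double* src = src0 + (std::size_t)wo * Ho;
          double* dstc = xc + (std::size_t)in_j * H;
          if (stride == 1) {
            int lo = std::max(0, pad - kh);
            int hi = std::min(Ho, H + pad - kh);
            double* d = dstc + lo + kh - pad;
            for (int ho = lo; ho < hi; ++ho) d[ho - lo] += src[ho];
          } else {
            for (int ho = 0; ho < Ho; ++ho) {
              int in_i = ho * stride + kh - pad;
              if (in_i >= 0 && in_i < H) dstc[in_i] += src[ho];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector w, NumericVector b,
                           int stride, int pad) {
  int xd[4], wd[4];
  get_dims4(x, xd); get_dims4(w, wd);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int KH = wd[0], KW = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv: channel mismatch");
  int Ho = (H + 2 * pad - KH) / stride + 1;
  int Wo = (W + 2 * pad - KW) / stride + 1;
  NumericVector y = alloc4(Ho, Wo, Cout, N);
  arma::mat Wmat(const_cast<double*>(w.begin()), KH * KW * Cin, Cout, false, true);
  arma::rowvec bv(const_cast<double*>(b.begin()), Cout, false, true);
  bool pointwise = (KH == 1 && KW == 1 && pad == 0);
  arma::mat colT;
  if (!pointwise) colT.set_size(Ho * Wo, KH * KW * Cin);
  for (int n = 0; n < N; ++n) {
    arma::mat yn(y.begin() + (std::size_t)n * Ho * Wo * Cout, Ho * Wo, Cout,
                 false, true);
    if (pointwise && stride == 1) {
      // 1x1 convolution is a plain channel-mixing gemm
      arma::mat xn(const_cast<double*>(x.begin()) + (std::size_t)n * H * W * C,
                   H * W, C, false, true);
      yn = xn * Wmat;
    } else if (pointwise) {
      arma::mat xs(Ho * Wo, C);
      const double* xb = x.begin() + (std::size_t)n * H * W * C;
      for (int ci = 0; ci < C; ++ci) {
        double* d = xs.colptr(ci);
        const double* s = xb + (std::size_t)ci * H * W;
        for (int wo = 0; wo < Wo; ++wo)
          for (int ho = 0; ho < Ho; ++ho)
            d[ho + (std::size_t)wo * Ho] =
              s[(std::size_t)(wo * stride) * H + ho * stride];
      }
      yn = xs * Wmat;
    } else {
      im2col(x.begin() + (std::size_t)n * H * W * C, H, W, C, KH, KW, pad,
             stride, Ho, Wo, colT);
      yn = colT * Wmat;
    }
    yn.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericVector w, NumericVector dy,
                  int stride, int pad) {
  int xd[4], wd[4], yd[4];
  get_dims4(x, xd); get_dims4(w, wd); get_dims4(dy, yd);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int KH = wd[0], KW = wd[1], Cout = wd[3];
  int Ho = yd[0], Wo = yd[1];
  NumericVector dx = alloc4(H, W, C, N);
  NumericVector dw = alloc4(KH, KW, C, Cout);
  NumericVector db(Cout);
  arma::mat Wmat(const_cast<double*>(w.begin()), KH * KW * C, Cout, false, true);
  arma::mat dWmat(dw.begin(), KH * KW * C, Cout, false, true);
  arma::rowvec dbv(db.begin(), Cout, false, true);
  bool pointwise = (KH == 1 && KW == 1 && pad == 0);
  arma::mat colT;
  if (!pointwise) colT.set_size(Ho * Wo, KH * KW * C);
  for (int n = 0; n < N; ++n) {
    arma::mat dyn(const_cast<double*>(dy.begin()) + (std::size_t)n * Ho * Wo * Cout,
                  Ho * Wo, Cout, false, true);
    dbv += arma::sum(dyn, 0);
    if (pointwise && stride == 1) {
      arma::mat xn(const_cast<double*>(x.begin()) + (std::size_t)n * H * W * C,
                   H * W, C, false, true);
      arma::mat dxn(dx.begin() + (std::size_t)n * H * W * C, H * W, C,
                    false, true);
      dWmat += xn.t() * dyn;
      dxn += dyn * Wmat.t();
    } else if (pointwise) {
      arma::mat xs(Ho * Wo, C);
      const double* xb = x.begin() + (std::size_t)n * H * W * C;
      for (int ci = 0; ci < C; ++ci) {
        double* d = xs.colptr(ci);
        const double* s = xb + (std::size_t)ci * H * W;
        for (int wo = 0; wo < Wo; ++wo)
          for (int ho = 0; ho < Ho; ++ho)
            d[ho + (std::size_t)wo * Ho] =
              s[(std::size_t)(wo * stride) * H + ho * stride];
      }
      dWmat += xs.t() * dyn;
      arma::mat dxs = dyn * Wmat.t();
      double* dxb = dx.begin() + (std::size_t)n * H * W * C;
      for (int ci = 0; ci < C; ++ci) {
        const double* s = dxs.colptr(ci);
        double* d = dxb + (std::size_t)ci * H * W;
        for (int wo = 0; wo < Wo; ++wo)
          for (int ho = 0; ho < Ho; ++ho)
            d[(std::size_t)(wo * stride) * H + ho * stride] +=
              s[ho + (std::size_t)wo * Ho];
      }
    } else {
      im2col(x.begin() + (std::size_t)n * H * W * C, H, W, C, KH, KW, pad,
             stride, Ho, Wo, colT);
      dWmat += colT.t() * dyn;
      arma::mat dcolT = dyn * Wmat.t();
      col2im_acc(dcolT, dx.begin() + (std::size_t)n * H * W * C, H, W, C,
                 KH, KW, pad, stride, Ho, Wo);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 stride-2 transposed convolution (non-overlapping upsampling).
// w: [2, 2, Cin, Cout]; y[2i+a, 2j+b, co] = sum_ci x[i,j,ci] w[a,b,ci,co] + b[co]
// [[Rcpp::export]]
NumericVector cpp_tconv2_fwd(NumericVector x, NumericVector w, NumericVector b) {
  int xd[4], wd[4];
  get_dims4(x, xd); get_dims4(w, wd);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Cout = wd[3];
  if (wd[0] != 2 || wd[1] != 2 || wd[2] != C) stop("tconv2: bad weight shape");
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector y = alloc4(Ho, Wo, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::mat xn(const_cast<double*>(x.begin()) + (std::size_t)n * H * W * C,
                 H * W, C, false, true);
    for (int a = 0; a < 2; ++a) {
      for (int bb = 0; bb < 2; ++bb) {
        // Wab: Cin x Cout slice at kernel position (a, bb)
        arma::mat Wab(C, Cout);
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < C; ++ci)
            Wab(ci, co) = w[a + 2 * (bb + 2 * (ci + (std::size_t)C * co))];
        arma::mat part = xn * Wab; // (H*W) x Cout
        for (int co = 0; co < Cout; ++co) {
          double* yc = y.begin() +
            (std::size_t)n * Ho * Wo * Cout + (std::size_t)co * Ho * Wo;
          const double* pc = part.colptr(co);
          double bco = b[co];
          for (int j = 0; j < W; ++j) {
            double* ycol = yc + (std::size_t)(2 * j + bb) * Ho + a;
            const double* pcol = pc + (std::size_t)j * H;
            for (int i = 0; i < H; ++i) ycol[2 * i] = pcol[i] + bco;
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_tconv2_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  int xd[4], wd[4];
  get_dims4(x, xd); get_dims4(w, wd);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Cout = wd[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector dx = alloc4(H, W, C, N);
  NumericVector dw = alloc4(2, 2, C, Cout);
  NumericVector db(Cout);
  for (int n = 0; n < N; ++n) {
    arma::mat xn(const_cast<double*>(x.begin()) + (std::size_t)n * H * W * C,
                 H * W, C, false, true);
    arma::mat dxn(dx.begin() + (std::size_t)n * H * W * C, H * W, C, false, true);
    for (int a = 0; a < 2; ++a) {
      for (int bb = 0; bb < 2; ++bb) {
        arma::mat dpart(H * W, Cout);
        for (int co = 0; co < Cout; ++co) {
          const double* dyc = dy.begin() +
            (std::size_t)n * Ho * Wo * Cout + (std::size_t)co * Ho * Wo;
          double* dpc = dpart.colptr(co);
          double acc = 0.0;
          for (int j = 0; j < W; ++j) {
            const double* dycol = dyc + (std::size_t)(2 * j + bb) * Ho + a;
            double* dpcol = dpc + (std::size_t)j * H;
            for (int i = 0; i < H; ++i) { dpcol[i] = dycol[2 * i]; acc += dycol[2 * i]; }
          }
          db[co] += acc;
        }
        arma::mat Wab(C, Cout);
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < C; ++ci)
            Wab(ci, co) = w[a + 2 * (bb + 2 * (ci + (std::size_t)C * co))];
        dxn += dpart * Wab.t();
        arma::mat dWab = xn.t() * dpart; // C x Cout
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < C; ++ci)
            dw[a + 2 * (bb + 2 * (ci + (std::size_t)C * co))] += dWab(ci, co);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 stride-2 max pooling with argmax bookkeeping for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  int xd[4];
  get_dims4(x, xd);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y = alloc4(Ho, Wo, C, N);
  IntegerVector idx = alloc4i(Ho, Wo, C, N); // 0-based linear index into x
  const double* px = x.begin();
  double* py = y.begin();
  int* pidx = idx.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      std::size_t xoff = ((std::size_t)n * C + c) * H * W;
      std::size_t yoff = ((std::size_t)n * C + c) * Ho * Wo;
      for (int jo = 0; jo < Wo; ++jo) {
        for (int io = 0; io < Ho; ++io) {
          std::size_t base = xoff + (std::size_t)(2 * jo) * H + 2 * io;
          std::size_t cand[4] = {base, base + 1, base + H, base + H + 1};
          std::size_t best = cand[0];
          for (int k = 1; k < 4; ++k) if (px[cand[k]] > px[best]) best = cand[k];
          py[yoff + (std::size_t)jo * Ho + io] = px[best];
          pidx[yoff + (std::size_t)jo * Ho + io] = (int)best;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(IntegerVector idx, NumericVector dy,
                               int H, int W) {
  int yd[4];
  get_dims4(dy, yd);
  int C = yd[2], N = yd[3];
  NumericVector dx = alloc4(H, W, C, N);
  const double* pdy = dy.begin();
  const int* pidx = idx.begin();
  double* pdx = dx.begin();
  std::size_t total = (std::size_t)yd[0] * yd[1] * C * N;
  for (std::size_t k = 0; k < total; ++k) pdx[pidx[k]] += pdy[k];
  return dx;
}

// Batch normalization over (H, W, N) per channel.
// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                double eps) {
  int xd[4];
  get_dims4(x, xd);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  std::size_t plane = (std::size_t)H * W;
  double m = (double)plane * N;
  NumericVector y = alloc4(H, W, C, N);
  NumericVector mean(C), var(C), invstd(C);
  const double* px = x.begin();
  double* py = y.begin();
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* p = px + ((std::size_t)n * C + c) * plane;
      for (std::size_t k = 0; k < plane; ++k) { s += p[k]; s2 += p[k] * p[k]; }
    }
    double mu = s / m;
    double v = s2 / m - mu * mu;
    if (v < 0) v = 0;
    double is = 1.0 / std::sqrt(v + eps);
    mean[c] = mu; var[c] = v; invstd[c] = is;
    double g = gamma[c], b = beta[c];
    for (int n = 0; n < N; ++n) {
      const double* p = px + ((std::size_t)n * C + c) * plane;
      double* q = py + ((std::size_t)n * C + c) * plane;
      for (std::size_t k = 0; k < plane; ++k) q[k] = g * (p[k] - mu) * is + b;
    }
  }
  return List::create(_["y"] = y, _["mean"] = mean, _["var"] = var,
                      _["invstd"] = invstd);
}

// [[Rcpp::export]]
NumericVector cpp_bn_eval(NumericVector x, NumericVector gamma,
                          NumericVector beta, NumericVector rmean,
                          NumericVector rvar, double eps) {
  int xd[4];
  get_dims4(x, xd);
  int C = xd[2], N = xd[3];
  std::size_t plane = (std::size_t)xd[0] * xd[1];
  NumericVector y = alloc4(xd[0], xd[1], C, N);
  const double* px = x.begin();
  double* py = y.begin();
  for (int c = 0; c < C; ++c) {
    double is = 1.0 / std::sqrt(rvar[c] + eps);
    double g = gamma[c], b = beta[c], mu = rmean[c];
    for (int n = 0; n < N; ++n) {
      const double* p = px + ((std::size_t)n * C + c) * plane;
      double* q = py + ((std::size_t)n * C + c) * plane;
      for (std::size_t k = 0; k < plane; ++k) q[k] = g * (p[k] - mu) * is + b;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector x, NumericVector dy, NumericVector gamma,
                NumericVector mean, NumericVector invstd) {
  int xd[4];
  get_dims4(x, xd);
  int C = xd[2], N = xd[3];
  std::size_t plane = (std::size_t)xd[0] * xd[1];
  double m = (double)plane * N;
  NumericVector dx = alloc4(xd[0], xd[1], C, N);
  NumericVector dgamma(C), dbeta(C);
  const double* px = x.begin();
  const double* pdy = dy.begin();
  double* pdx = dx.begin();
  for (int c = 0; c < C; ++c) {
    double mu = mean[c], is = invstd[c], g = gamma[c];
    double sum_dy = 0, sum_dy_xhat = 0;
    for (int n = 0; n < N; ++n) {
      std::size_t off = ((std::size_t)n * C + c) * plane;
      for (std::size_t k = 0; k < plane; ++k) {
        double xhat = (px[off + k] - mu) * is;
        sum_dy += pdy[off + k];
        sum_dy_xhat += pdy[off + k] * xhat;
      }
    }
    dbeta[c] = sum_dy;
    dgamma[c] = sum_dy_xhat;
    double a1 = sum_dy / m, a2 = sum_dy_xhat / m;
    for (int n = 0; n < N; ++n) {
      std::size_t off = ((std::size_t)n * C + c) * plane;
      for (std::size_t k = 0; k < plane; ++k) {
        double xhat = (px[off + k] - mu) * is;
        pdx[off + k] = g * is * (pdy[off + k] - a1 - xhat * a2);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
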