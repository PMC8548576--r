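// Low-level numeric kernels for the detector's network engine.
// Tensor layout everywhere: column-major R arrays dim = (H, W, C, N).
// Convolution weights: dim = (k, k, Cin, Cout); flattening that array
// column-major gives exactly the (k*k*Cin) x Cout matrix used by the
// im2col GEMM, so no reordering is ever needed on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d (H,W,C,N) array");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// Gather one sample (H x W x Cin slab at offset) into cols (kkC x HoWo).
static void im2col_one(const double* xp, int H, int W, int Cin,
                       int k, int stride, int pad, int Ho, int Wo,
                       arma::mat& cols) {
  const int HW = H * W;
  const size_t kkC = (size_t)k * k * Cin;
  double* base = cols.memptr();
  for (int c = 0; c < Cin; ++c) {
    const double* xc = xp + (size_t)c * HW;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const size_t r = (size_t)kh + k * kw + (size_t)k * k * c;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride + kw - pad;
          double* dst = base + r + kkC * (size_t)Ho * wo;
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Ho; ++ho, dst += kkC) *dst = 0.0;
            continue;
          }
          const double* xcol = xc + (size_t)wi * H;
          for (int ho = 0; ho < Ho; ++ho, dst += kkC) {
            const int hi = ho * stride + kh - pad;
            *dst = (hi < 0 || hi >= H) ? 0.0 : xcol[hi];
          }
        }
      }
    }
  }
}

// Scatter-accumulate cols back into dx for one sample.
static void col2im_one(const arma::mat& cols, int H, int W, int Cin,
                       int k, int stride, int pad, int Ho, int Wo,
                       double* dxp) {
  const int HW = H * W;
  const size_t kkC = (size_t)k * k * Cin;
  const double* base = cols.memptr();
  for (int c = 0; c < Cin; ++c) {
    double* xc = dxp + (size_t)c * HW;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const size_t r = (size_t)kh + k * kw + (size_t)k * k * c;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride + kw - pad;
          if (wi < 0 || wi >= W) continue;
          double* xcol = xc + (size_t)wi * H;
          const double* src = base + r + kkC * (size_t)Ho * wo;
          for (int ho = 0; ho < Ho; ++ho, src += kkC) {
            const int hi = ho * stride + kh - pad;
            if (hi < 0 || hi >= H) continue;
            xcol[hi] += *src;
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w,
                             int stride, int pad) {
  int H, W, Cin, N; get_dims4(x, H, W, Cin, N);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4) stop("weight must be (k,k,Cin,Cout)");
  int k = wd[0], Cin_w = wd[2], Cout = wd[3];
  if (wd[1] != k) stop("non-square kernel");
  if (Cin_w != Cin) stop("input has %d channels but kernel expects %d", Cin, Cin_w);
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("non-positive output spatial size");

  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * Cin, Cout, false, true);
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat cols((size_t)k * k * Cin, (size_t)Ho * Wo);
  const size_t xs = (size_t)H * W * Cin, ys = (size_t)Ho * Wo * Cout;
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + n * xs, H, W, Cin, k, stride, pad, Ho, Wo, cols);
    arma::mat Yn(y.begin() + n * ys, (size_t)Ho * Wo, Cout, false, true);
    Yn = cols.t() * Wm;
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad) {
  int H, W, Cin, N; get_dims4(x, H, W, Cin, N);
  IntegerVector wd = w.attr("dim");
  int k = wd[0], Cout = wd[3];
  int Ho, Wo, Cdy, Ndy; get_dims4(dy, Ho, Wo, Cdy, Ndy);
  if (Cdy != Cout || Ndy != N) stop("dy shape mismatch");

  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * Cin, Cout, false, true);
  NumericVector dx((size_t)H * W * Cin * N);
  dx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  arma::mat dWm(dw.begin(), (size_t)k * k * Cin, Cout, false, true);

  arma::mat cols((size_t)k * k * Cin, (size_t)Ho * Wo);
  const size_t xs = (size_t)H * W * Cin, ys = (size_t)Ho * Wo * Cout;
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + n * xs, H, W, Cin, k, stride, pad, Ho, Wo, cols);
    arma::mat dYn(const_cast<double*>(dy.begin()) + n * ys,
                  (size_t)Ho * Wo, Cout, false, true);
    dWm += cols * dYn;
    arma::mat dcols = Wm * dYn.t();
    col2im_one(dcols, H, W, Cin, k, stride, pad, Ho, Wo, dx.begin() + n * xs);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// Batch norm over (H, W, N) per channel.
// [[Rcpp::export]]
List bn_fwd_cpp(NumericVector x, NumericVector gamma, NumericVector beta,
                NumericVector rmean, NumericVector rvar,
                double eps, double momentum, bool training) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  const size_t HW = (size_t)H * W, CS = HW * C;
  NumericVector y(x.size()); y.attr("dim") = x.attr("dim");
  NumericVector mu(C), invstd(C), rm(C), rv(C);
  const double m = (double)HW * N;
  for (int c = 0; c < C; ++c) {
    double mean_c, var_c;
    if (training) {
      double s = 0.0, s2 = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* p = x.begin() + n * CS + c * HW;
        for (size_t i = 0; i < HW; ++i) { s += p[i]; s2 += p[i] * p[i]; }
      }
      mean_c = s / m;
      var_c = s2 / m - mean_c * mean_c;
      if (var_c < 0) var_c = 0;
      rm[c] = (1.0 - momentum) * rmean[c] + momentum * mean_c;
      // unbiased running variance, torch/darknet convention
      double ub = (m > 1.0) ? var_c * m / (m - 1.0) : var_c;
      rv[c] = (1.0 - momentum) * rvar[c] + momentum * ub;
    } else {
      mean_c = rmean[c]; var_c = rvar[c];
      rm[c] = rmean[c]; rv[c] = rvar[c];
    }
    const double is = 1.0 / std::sqrt(var_c + eps);
    mu[c] = mean_c; invstd[c] = is;
    const double g = gamma[c] * is, b = beta[c] - gamma[c] * is * mean_c;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + n * CS + c * HW;
      double* q = y.begin() + n * CS + c * HW;
      for (size_t i = 0; i < HW; ++i) q[i] = g * p[i] + b;
    }
  }
  return List::create(_["y"] = y, _["mean"] = mu, _["invstd"] = invstd,
                      _["rmean"] = rm, _["rvar"] = rv);
}

// [[Rcpp::export]]
List bn_bwd_cpp(NumericVector x, NumericVector gamma,
                NumericVector mean, NumericVector invstd,
                NumericVector dy, bool training) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  const size_t HW = (size_t)H * W, CS = HW * C;
  NumericVector dx(x.size()); dx.attr("dim") = x.attr("dim");
  NumericVector dgamma(C), dbeta(C);
  const double m = (double)HW * N;
  for (int c = 0; c < C; ++c) {
    const double mu = mean[c], is = invstd[c];
    double sdy = 0.0, sdyx = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* px = x.begin() + n * CS + c * HW;
      const double* pd = dy.begin() + n * CS + c * HW;
      for (size_t i = 0; i < HW; ++i) {
        sdy += pd[i];
        sdyx += pd[i] * (px[i] - mu) * is;
      }
    }
    dgamma[c] = sdyx; dbeta[c] = sdy;
    if (training) {
      const double g = gamma[c];
      for (int n = 0; n < N; ++n) {
        const double* px = x.begin() + n * CS + c * HW;
        const double* pd = dy.begin() + n * CS + c * HW;
        double* pq = dx.begin() + n * CS + c * HW;
        for (size_t i = 0; i < HW; ++i) {
          const double xhat = (px[i] - mu) * is;
          pq[i] = g * is * (pd[i] - sdy / m - xhat * sdyx / m);
        }
      }
    } else {
      const double g = gamma[c] * is;
      for (int n = 0; n < N; ++n) {
        const double* pd = dy.begin() + n * CS + c * HW;
        double* pq = dx.begin() + n * CS + c * HW;
        for (size_t i = 0; i < HW; ++i) pq[i] = g * pd[i];
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// 2x2 stride-2 max pool; idx records 0-based linear offsets into x.
// [[Rcpp::export]]
List maxpool2_fwd_cpp(NumericVector x) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  if (H % 2 || W % 2) stop("maxpool2 requires even spatial dims");
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size());
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          size_t best = base + (size_t)(2 * wo) * H + 2 * ho;
          double bv = x[best];
          const size_t cand[3] = { base + (size_t)(2 * wo) * H + 2 * ho + 1,
                                   base + (size_t)(2 * wo + 1) * H + 2 * ho,
                                   base + (size_t)(2 * wo + 1) * H + 2 * ho + 1 };
          for (int t = 0; t < 3; ++t)
            if (x[cand[t]] > bv) { bv = x[cand[t]]; best = cand[t]; }
          // output linear index in (Ho,Wo) order within this (c,n) slab
          size_t oi = ((size_t)n * C + c) * Ho * Wo + (size_t)wo * Ho + ho;
          y[oi] = bv; idx[oi] = (int)best;
          (void)o;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(NumericVector dy, IntegerVector idx,
                               IntegerVector xdim) {
  size_t nx = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(nx); dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i]] += dy[i];
  return dx;
}

// Nearest-neighbour 2x upsample.
// [[Rcpp::export]]
NumericVector upsample2_fwd_cpp(NumericVector x) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + ((size_t)n * C + c) * H * W;
      double* q = y.begin() + ((size_t)n * C + c) * Ho * Wo;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const double v = p[(size_t)w * H + h];
          const size_t b = (size_t)(2 * w) * Ho + 2 * h;
          q[b] = v; q[b + 1] = v; q[b + Ho] = v; q[b + Ho + 1] = v;
        }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2_bwd_cpp(NumericVector dy) {
  int Ho, Wo, C, N; get_dims4(dy, Ho, Wo, C, N);
  int H = Ho / 2, W = Wo / 2;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* p = dx.begin() + ((size_t)n * C + c) * H * W;
      const double* q = dy.begin() + ((size_t)n * C + c) * Ho * Wo;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const size_t b = (size_t)(2 * w) * Ho + 2 * h;
          p[(size_t)w * H + h] = q[b] + q[b + 1] + q[b + Ho] + q[b + Ho + 1];
        }
    }
  return dx;
}

// Max over the channel dimension -> (H,W,1,N), argmax channel recorded.
// [[Rcpp::export]]
List chmax_fwd_cpp(NumericVector x) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  const size_t HW = (size_t)H * W;
  NumericVector y(HW * N); y.attr("dim") = IntegerVector::create(H, W, 1, N);
  IntegerVector idx(y.size());
  for (int n = 0; n < N; ++n) {
    const double* p0 = x.begin() + (size_t)n * C * HW;
    double* q = y.begin() + (size_t)n * HW;
    int* ix = idx.begin() + (size_t)n * HW;
    for (size_t i = 0; i < HW; ++i) { q[i] = p0[i]; ix[i] = 0; }
    for (int c = 1; c < C; ++c) {
      const double* p = p0 + (size_t)c * HW;
      for (size_t i = 0; i < HW; ++i)
        if (p[i] > q[i]) { q[i] = p[i]; ix[i] = c; }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector chmax_bwd_cpp(NumericVector dy, IntegerVector idx, IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t HW = (size_t)H * W;
  NumericVector dx(HW * C * N); dx.attr("dim") = xdim;
  for (int n = 0; n < N; ++n) {
    const double* q = dy.begin() + (size_t)n * HW;
    const int* ix = idx.begin() + (size_t)n * HW;
    double* p0 = dx.begin() + (size_t)n * C * HW;
    for (size_t i = 0; i < HW; ++i) p0[(size_t)ix[i] * HW + i] += q[i];
  }
  return dx;
}

// Mean over the channel dimension -> (H,W,1,N).
// [[Rcpp::export]]
NumericVector chmean_fwd_cpp(NumericVector x) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  const size_t HW = (size_t)H * W;
  NumericVector y(HW * N); y.attr("dim") = IntegerVector::create(H, W, 1, N);
  for (int n = 0; n < N; ++n) {
    const double* p0 = x.begin() + (size_t)n * C * HW;
    double* q = y.begin() + (size_t)n * HW;
    for (int c = 0; c < C; ++c) {
      const double* p = p0 + (size_t)c * HW;
      for (size_t i = 0; i < HW; ++i) q[i] += p[i];
    }
    for (size_t i = 0; i < HW; ++i) q[i] /= C;
  }
  return y;
}

// Bilinear resize of an (H,W,C) image array; used for preprocessing only.
// [[Rcpp::export]]
NumericVector resize_bilinear_cpp(NumericVector x, int oh, int ow) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("expected (H,W,C) image array");
  int H = d[0], W = d[1], C = d[2];
  NumericVector y((size_t)oh * ow * C);
  y.attr("dim") = IntegerVector::create(oh, ow, C);
  const double sh = (double)H / oh, sw = (double)W / ow;
  for (int c = 0; c < C; ++c) {
    const double* p = x.begin() + (size_t)c * H * W;
    double* q = y.begin() + (size_t)c * oh * ow;
    for (int wo = 0; wo < ow; ++wo) {
      double fw = (wo + 0.5) * sw - 0.5;
      int w0 = (int)std::floor(fw); double tw = fw - w0;
      int w1 = w0 + 1;
      if (w0 < 0) { w0 = 0; w1 = 0; tw = 0; }
      if (w1 >= W) { w1 = W - 1; if (w0 >= W) w0 = W - 1; }
      for (int ho = 0; ho < oh; ++ho) {
        double fh = (ho + 0.5) * sh - 0.5;
        int h0 = (int)std::floor(fh); double th = fh - h0;
        int h1 = h0 + 1;
        if (h0 < 0) { h0 = 0; h1 = 0; th = 0; }
        if (h1 >= H) { h1 = H - 1; if (h0 >= H) h0 = H - 1; }
        const double v =
          (1 - tw) * ((1 - th) * p[(size_t)w0 * H + h0] + th * p[(size_t)w0 * H + h1]) +
          tw * ((1 - th) * p[(size_t)w1 * H + h0] + th * p[(size_t)w1 * H + h1]);
        q[(size_t)wo * oh + ho] = v;
      }
    }
  }
  return y;
}

// Leaky ReLU forward/backward (mask recomputed from x in backward).
// [[Rcpp::export]]
NumericVector leaky_fwd_cpp(NumericVector x, double slope) {
  NumericVector y(x.size()); y.attr("dim") = x.attr("dim");
  const double* p = x.begin(); double* q = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i)
    q[i] = p[i] >= 0 ? p[i] : slope * p[i];
  return y;
}

// [[Rcpp::export]]
NumericVector leaky_bwd_cpp(NumericVector x, NumericVector g, double slope) {
  NumericVector d(x.size()); d.attr("dim") = x.attr("dim");
  const double* p = x.begin(); const double* pg = g.begin();
  double* q = d.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i)
    q[i] = p[i] >= 0 ? pg[i] : slope * pg[i];
  return d;
}

// Pixel-wise gating: y = x * gate with gate (H, W, 1, N).
// [[Rcpp::export]]
NumericVector scale_spatial_fwd_cpp(NumericVector x, NumericVector gate) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  const size_t HW = (size_t)H * W;
  NumericVector y(x.size()); y.attr("dim") = x.attr("dim");
  for (int n = 0; n < N; ++n) {
    const double* gp = gate.begin() + (size_t)n * HW;
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + ((size_t)n * C + c) * HW;
      double* q = y.begin() + ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) q[i] = p[i] * gp[i];
    }
  }
  return y;
}

// [[Rcpp::export]]
List scale_spatial_bwd_cpp(NumericVector x, NumericVector gate,
                           NumericVector g) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  const size_t HW = (size_t)H * W;
  NumericVector dx(x.size()); dx.attr("dim") = x.attr("dim");
  NumericVector dgate(HW * N);
  dgate.attr("dim") = IntegerVector::create(H, W, 1, N);
  for (int n = 0; n < N; ++n) {
    const double* gp = gate.begin() + (size_t)n * HW;
    double* dg = dgate.begin() + (size_t)n * HW;
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + ((size_t)n * C + c) * HW;
      const double* pg = g.begin() + ((size_t)n * C + c) * HW;
      double* q = dx.begin() + ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) {
        q[i] = pg[i] * gp[i];
        dg[i] += pg[i] * p[i];
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgate"] = dgate);
}
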