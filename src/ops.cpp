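// Low-level array ops for the segmentation network and component labelling.
// Feature arrays are R double arrays with dim (H, W, C, N), column-major.
// Convolutions are cross-correlations (CNN convention) with zero padding.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline IntegerVector alloc4i(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline void get_dims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a rank-4 array (H, W, C, N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// im2col for one sample: x (H,W,C) -> cols (kh*kw*C x H*W), zero padded.
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int padh, int padw, arma::mat& cols) {
  const int HW = H * W;
  cols.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * HW;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int row = ki + kh * (kj + kw * c);
        for (int ow = 0; ow < W; ++ow) {
          const int iw = ow + kj - padw;
          if (iw < 0 || iw >= W) continue;
          const double* src = xc + (size_t)iw * H;
          double* dst = cols.memptr() + (size_t)row + (size_t)cols.n_rows * (size_t)ow * H;
          for (int oh = 0; oh < H; ++oh) {
            const int ih = oh + ki - padh;
            if (ih < 0 || ih >= H) continue;
            dst[(size_t)oh * cols.n_rows] = src[ih];
          }
        }
      }
    }
  }
}

// accumulate cols (kh*kw*C x H*W) back into gx (H,W,C) (adjoint of im2col)
static void col2im_acc(const arma::mat& cols, int H, int W, int C,
                       int kh, int kw, int padh, int padw, double* gx) {
  const int HW = H * W;
  for (int c = 0; c < C; ++c) {
    double* gc = gx + (size_t)c * HW;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int row = ki + kh * (kj + kw * c);
        for (int ow = 0; ow < W; ++ow) {
          const int iw = ow + kj - padw;
          if (iw < 0 || iw >= W) continue;
          double* dst = gc + (size_t)iw * H;
          const double* src = cols.memptr() + (size_t)row + (size_t)cols.n_rows * (size_t)ow * H;
          for (int oh = 0; oh < H; ++oh) {
            const int ih = oh + ki - padh;
            if (ih < 0 || ih >= H) continue;
            dst[ih] += src[(size_t)oh * cols.n_rows];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_conv2d_fw")]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w,
                            Nullable<NumericVector> bias, int padh, int padw) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4 || wd[2] != C)
    stop("kernel must have dim (kh, kw, %d, D); got input channel mismatch", C);
  const int kh = wd[0], kw = wd[1], D = wd[3];
  const int K = kh * kw * C, HW = H * W;

  NumericVector y = alloc4(H, W, D, N);
  arma::mat Wm(w.begin(), K, D, false, true);   // column d = vec kernel d
  arma::mat cols(K, HW);
  arma::vec b;
  if (bias.isNotNull()) b = as<arma::vec>(bias.get());

  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * HW * C, H, W, C, kh, kw, padh, padw, cols);
    arma::mat Yn(y.begin() + (size_t)n * HW * D, HW, D, false, true);
    Yn = cols.t() * Wm;
    if (b.n_elem) Yn.each_row() += b.t();
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_conv2d_bw")]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector gy,
                   int padh, int padw, bool need_gx, bool need_gb) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], D = wd[3];
  const int K = kh * kw * C, HW = H * W;

  arma::mat Wm(w.begin(), K, D, false, true);
  NumericVector gw = alloc4(kh, kw, C, D);
  arma::mat gWm(gw.begin(), K, D, false, true);
  NumericVector gx;
  if (need_gx) gx = alloc4(H, W, C, N);
  arma::vec gb(D, arma::fill::zeros);
  arma::mat cols(K, HW);

  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * HW * C, H, W, C, kh, kw, padh, padw, cols);
    arma::mat Gn((double*)gy.begin() + (size_t)n * HW * D, HW, D, false, true);
    gWm += cols * Gn;
    if (need_gb) gb += arma::sum(Gn, 0).t();
    if (need_gx) {
      arma::mat gcols = Wm * Gn.t();   // K x HW
      col2im_acc(gcols, H, W, C, kh, kw, padh, padw,
                 gx.begin() + (size_t)n * HW * C);
    }
  }
  List out = List::create(_["gw"] = gw);
  if (need_gx) out["gx"] = gx;
  if (need_gb) out["gb"] = NumericVector(gb.begin(), gb.end());
  return out;
}

// transpose convolution, kernel 2x2, stride 2: (H,W,C,N) -> (2H,2W,D,N)
// w has dim (2, 2, C, D)
// [[Rcpp::export(name = ".cpp_upconv2_fw")]]
NumericVector cpp_upconv2_fw(NumericVector x, NumericVector w,
                             Nullable<NumericVector> bias) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  if (wd[0] != 2 || wd[1] != 2 || wd[2] != C) stop("upconv kernel must be (2,2,C,D)");
  const int D = wd[3], HW = H * W, H2 = 2 * H, W2 = 2 * W;

  // V (C x 4D): V[c, a + 2b + 4d] = w[a,b,c,d]
  arma::mat V(C, 4 * D);
  for (int d = 0; d < D; ++d)
    for (int c = 0; c < C; ++c)
      for (int b = 0; b < 2; ++b)
        for (int a = 0; a < 2; ++a)
          V(c, a + 2 * b + 4 * d) = w[a + 2 * (b + 2 * ((size_t)c + (size_t)C * d))];

  NumericVector y = alloc4(H2, W2, D, N);
  arma::vec bv;
  if (bias.isNotNull()) bv = as<arma::vec>(bias.get());

  for (int n = 0; n < N; ++n) {
    arma::mat Xn((double*)x.begin() + (size_t)n * HW * C, HW, C, false, true);
    arma::mat Y4 = Xn * V;     // HW x 4D
    double* yn = y.begin() + (size_t)n * H2 * W2 * D;
    for (int d = 0; d < D; ++d) {
      const double bd = bv.n_elem ? bv[d] : 0.0;
      double* yd = yn + (size_t)d * H2 * W2;
      for (int b = 0; b < 2; ++b)
        for (int a = 0; a < 2; ++a) {
          const double* col = Y4.colptr(a + 2 * b + 4 * d);
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i)
              yd[(size_t)(2 * i + a) + (size_t)H2 * (2 * j + b)] = col[i + H * j] + bd;
        }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_upconv2_bw")]]
List cpp_upconv2_bw(NumericVector x, NumericVector w, NumericVector gy) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  const int D = wd[3], HW = H * W, H2 = 2 * H, W2 = 2 * W;

  arma::mat V(C, 4 * D);
  for (int d = 0; d < D; ++d)
    for (int c = 0; c < C; ++c)
      for (int b = 0; b < 2; ++b)
        for (int a = 0; a < 2; ++a)
          V(c, a + 2 * b + 4 * d) = w[a + 2 * (b + 2 * ((size_t)c + (size_t)C * d))];

  arma::mat gV(C, 4 * D, arma::fill::zeros);
  arma::vec gb(D, arma::fill::zeros);
  NumericVector gx = alloc4(H, W, C, N);
  arma::mat G4(HW, 4 * D);

  for (int n = 0; n < N; ++n) {
    const double* gyn = gy.begin() + (size_t)n * H2 * W2 * D;
    for (int d = 0; d < D; ++d) {
      const double* gd = gyn + (size_t)d * H2 * W2;
      double acc = 0.0;
      for (int b = 0; b < 2; ++b)
        for (int a = 0; a < 2; ++a) {
          double* col = G4.colptr(a + 2 * b + 4 * d);
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i) {
              const double g = gd[(size_t)(2 * i + a) + (size_t)H2 * (2 * j + b)];
              col[i + H * j] = g;
              acc += g;
            }
        }
      gb[d] += acc;
    }
    arma::mat Xn((double*)x.begin() + (size_t)n * HW * C, HW, C, false, true);
    gV += Xn.t() * G4;
    arma::mat gXn(gx.begin() + (size_t)n * HW * C, HW, C, false, true);
    gXn = G4 * V.t();
  }

  NumericVector gw = alloc4(2, 2, C, D);
  for (int d = 0; d < D; ++d)
    for (int c = 0; c < C; ++c)
      for (int b = 0; b < 2; ++b)
        for (int a = 0; a < 2; ++a)
          gw[a + 2 * (b + 2 * ((size_t)c + (size_t)C * d))] = gV(c, a + 2 * b + 4 * d);

  return List::create(_["gx"] = gx, _["gw"] = gw,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// 2x2 max pooling, stride 2; returns pooled values and 0-based argmax indices
// [[Rcpp::export(name = ".cpp_maxpool2_fw")]]
List cpp_maxpool2_fw(NumericVector x) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  if (H % 2 || W % 2) stop("spatial dims must be even for 2x2 pooling");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = alloc4(Ho, Wo, C, N);
  IntegerVector idx = alloc4i(Ho, Wo, C, N);
  const size_t plane = (size_t)H * W;
  size_t o = 0;
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* xp = x.begin() + cn * plane;
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i, ++o) {
        size_t base = (size_t)2 * i + (size_t)H * (2 * j);
        size_t cand[4] = { base, base + 1, base + H, base + H + 1 };
        size_t best = cand[0];
        double bv = xp[cand[0]];
        for (int k = 1; k < 4; ++k)
          if (xp[cand[k]] > bv) { bv = xp[cand[k]]; best = cand[k]; }
        y[o] = bv;
        idx[o] = (int)(best + cn * plane);
      }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_maxpool2_bw")]]
NumericVector cpp_maxpool2_bw(IntegerVector idx, NumericVector gy,
                              IntegerVector in_dim) {
  NumericVector gx = alloc4(in_dim[0], in_dim[1], in_dim[2], in_dim[3]);
  for (R_xlen_t k = 0; k < gy.size(); ++k) gx[idx[k]] += gy[k];
  return gx;
}

// connected-component labelling of a binary matrix, 4- or 8-connectivity
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerMatrix cpp_label_components(IntegerMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  const int dr4[4] = { -1, 1, 0, 0 }, dc4[4] = { 0, 0, -1, 1 };
  const int dr8[8] = { -1, 1, 0, 0, -1, -1, 1, 1 }, dc8[8] = { 0, 0, -1, 1, -1, 1, -1, 1 };
  const int* dr = connectivity == 4 ? dr4 : dr8;
  const int* dc = connectivity == 4 ? dc4 : dc8;
  const int nd = connectivity;
  for (int c0 = 0; c0 < W; ++c0)
    for (int r0 = 0; r0 < H; ++r0) {
      if (mask(r0, c0) == 0 || lab(r0, c0) != 0) continue;
      ++next;
      lab(r0, c0) = next;
      stack.push_back(r0 + H * c0);
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int r = p % H, c = p / H;
        for (int k = 0; k < nd; ++k) {
          const int rr = r + dr[k], cc = c + dc[k];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (mask(rr, cc) != 0 && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(rr + H * cc);
          }
        }
      }
    }
  return lab;
}

// ---- channel-wise helpers used by batch norm and the attention block ----

// per-channel mean and biased variance over (H, W, N)
// [[Rcpp::export(name = ".cpp_channel_stats")]]
List cpp_channel_stats(NumericVector x) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  const size_t plane = (size_t)H * W;
  arma::vec s(C, arma::fill::zeros), s2(C, arma::fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + plane * (c + (size_t)C * n);
      double a = 0, b = 0;
      for (size_t k = 0; k < plane; ++k) { a += p[k]; b += p[k] * p[k]; }
      s[c] += a; s2[c] += b;
    }
  const double M = (double)plane * N;
  arma::vec mu = s / M;
  arma::vec v = s2 / M - mu % mu;
  v.transform([](double z) { return z < 0 ? 0 : z; });
  return List::create(_["mean"] = NumericVector(mu.begin(), mu.end()),
                      _["var"] = NumericVector(v.begin(), v.end()));
}

// per-channel sums over (H, W, N)
// [[Rcpp::export(name = ".cpp_channel_sums")]]
NumericVector cpp_channel_sums(NumericVector x) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  const size_t plane = (size_t)H * W;
  NumericVector out(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + plane * (c + (size_t)C * n);
      double a = 0;
      for (size_t k = 0; k < plane; ++k) a += p[k];
      out[c] += a;
    }
  return out;
}

// y[,,c,n] = x[,,c,n] * A[c,n] + B[c,n]
// [[Rcpp::export(name = ".cpp_scale_shift_cn")]]
NumericVector cpp_scale_shift_cn(NumericVector x, NumericMatrix A,
                                 NumericMatrix B) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  if (A.nrow() != C || A.ncol() != N || B.nrow() != C || B.ncol() != N)
    stop("A and B must be C x N");
  const size_t plane = (size_t)H * W;
  NumericVector y = alloc4(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double a = A(c, n), b = B(c, n);
      const double* p = x.begin() + plane * (c + (size_t)C * n);
      double* q = y.begin() + plane * (c + (size_t)C * n);
      for (size_t k = 0; k < plane; ++k) q[k] = p[k] * a + b;
    }
  return y;
}

// out[c,n] = sum over (H,W) of x[,,c,n] * y[,,c,n]
// [[Rcpp::export(name = ".cpp_sum_prod_cn")]]
NumericMatrix cpp_sum_prod_cn(NumericVector x, NumericVector y) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  const size_t plane = (size_t)H * W;
  NumericMatrix out(C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + plane * (c + (size_t)C * n);
      const double* q = y.begin() + plane * (c + (size_t)C * n);
      double a = 0;
      for (size_t k = 0; k < plane; ++k) a += p[k] * q[k];
      out(c, n) = a;
    }
  return out;
}

// batch-norm backward in one pass: returns gx, dgamma, dbeta
// [[Rcpp::export(name = ".cpp_bn_bw")]]
List cpp_bn_bw(NumericVector xhat, NumericVector gy, NumericVector gamma,
               NumericVector inv, bool train) {
  int H, W, C, N;
  get_dims4(xhat, H, W, C, N);
  const size_t plane = (size_t)H * W;
  const double M = (double)plane * N;
  arma::vec dg(C, arma::fill::zeros), db(C, arma::fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xh = xhat.begin() + plane * (c + (size_t)C * n);
      const double* g = gy.begin() + plane * (c + (size_t)C * n);
      double a = 0, b = 0;
      for (size_t k = 0; k < plane; ++k) { a += g[k] * xh[k]; b += g[k]; }
      dg[c] += a; db[c] += b;
    }
  NumericVector gx = alloc4(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double sc = gamma[c] * inv[c];
      const double mg = dg[c] / M, mb = db[c] / M;
      const double* xh = xhat.begin() + plane * (c + (size_t)C * n);
      const double* g = gy.begin() + plane * (c + (size_t)C * n);
      double* q = gx.begin() + plane * (c + (size_t)C * n);
      if (train)
        for (size_t k = 0; k < plane; ++k)
          q[k] = sc * (g[k] - mb - xh[k] * mg);
      else
        for (size_t k = 0; k < plane; ++k) q[k] = sc * g[k];
    }
  return List::create(_["gx"] = gx,
                      _["dgamma"] = NumericVector(dg.begin(), dg.end()),
                      _["dbeta"] = NumericVector(db.begin(), db.end()));
}

// per-(channel, sample) spatial means: C x N
// [[Rcpp::export(name = ".cpp_mean_cn")]]
NumericMatrix cpp_mean_cn(NumericVector x) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  const size_t plane = (size_t)H * W;
  NumericMatrix out(C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + plane * (c + (size_t)C * n);
      double a = 0;
      for (size_t k = 0; k < plane; ++k) a += p[k];
      out(c, n) = a / plane;
    }
  return out;
}
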