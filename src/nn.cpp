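#include <RcppArmadillo.h>
using namespace Rcpp;

// Minimal CNN layer kernels used by the dual-decoder network.
//
// Tensors are R numeric arrays in (H, W, C, N) layout (column-major, so
// H is the fastest axis). 3x3 convolutions use same-padding and are
// evaluated as im2col + GEMM; 2x2 transposed convolutions have stride 2
// (no output overlap), so they reduce to a single GEMM plus a scatter.
// GEMMs run in single precision (weights, activations and gradients
// cross the R boundary as doubles); batch-norm statistics stay in
// double.

static inline IntegerVector dims4(const NumericVector &x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d (H,W,C,N) array");
  return d;
}

// im2col for one image: K is (H*W) x (9*Cin); column r = cin*9 + k with
// k = (dx+1)*3 + (dy+1) holds x(iz+dy, ix+dx, cin), zero outside.
static void im2col3(const double *x, int H, int W, int Cin, arma::fmat &K) {
  K.zeros();
  for (int cin = 0; cin < Cin; ++cin) {
    const double *xc = x + (size_t)H * W * cin;
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        const int r = cin * 9 + (dx + 1) * 3 + (dy + 1);
        float *kcol = K.colptr(r);
        for (int ix = 0; ix < W; ++ix) {
          const int sx = ix + dx;
          if (sx < 0 || sx >= W) continue;
          const double *src = xc + (size_t)H * sx;
          float *dst = kcol + (size_t)H * ix;
          const int z0 = std::max(0, -dy), z1 = std::min(H, H - dy);
          for (int iz = z0; iz < z1; ++iz) dst[iz] = (float)src[iz + dy];
        }
      }
    }
  }
}

// weight matrix (9*Cin) x Cout from w(3,3,Cin,Cout); row order matches
// im2col3 (dy fastest inside dx inside cin).
static arma::fmat wmatT3(const NumericVector &w, int Cin, int Cout) {
  arma::fmat Wt(9 * Cin, Cout);
  const double *wp = REAL(w);
  for (int cout = 0; cout < Cout; ++cout)
    for (int cin = 0; cin < Cin; ++cin)
      for (int dx = 0; dx < 3; ++dx)
        for (int dy = 0; dy < 3; ++dy)
          Wt(cin * 9 + dx * 3 + dy, cout) =
              (float)wp[dy + 3 * dx + 9 * cin + 9 * (size_t)Cin * cout];
  return Wt;
}

// [[Rcpp::export]]
NumericVector nn_conv_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], Cin = d[2], N = d[3];
  IntegerVector wd = w.attr("dim");
  const int Cout = wd[3];
  if (wd[2] != Cin) stop("conv: channel mismatch");
  NumericVector y((R_xlen_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::fmat K(H * W, 9 * Cin);
  arma::fmat Wt = wmatT3(w, Cin, Cout);
  const double *bp = REAL(b);
  const int HW = H * W;
  for (int n = 0; n < N; ++n) {
    im2col3(REAL(x) + (size_t)HW * Cin * n, H, W, Cin, K);
    arma::fmat Y = K * Wt; // (HW x Cout)
    double *yp = REAL(y) + (size_t)HW * Cout * n;
    for (int cout = 0; cout < Cout; ++cout) {
      const float *src = Y.colptr(cout);
      double *dst = yp + (size_t)HW * cout;
      const double bc = bp[cout];
      for (int p = 0; p < HW; ++p) dst[p] = (double)src[p] + bc;
    }
  }
  return y;
}

// [[Rcpp::export]]
List nn_conv_bw(NumericVector x, NumericVector w, NumericVector gy,
                bool need_gx = true) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], Cin = d[2], N = d[3];
  IntegerVector wd = w.attr("dim");
  const int Cout = wd[3];
  NumericVector gx((R_xlen_t)H * W * Cin * N);
  gx.attr("dim") = d;
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(Cout);
  const int HW = H * W;
  arma::fmat K(HW, 9 * Cin);
  arma::fmat GY(HW, Cout);
  arma::fmat Wt = wmatT3(w, Cin, Cout);
  arma::fmat gWt(9 * Cin, Cout, arma::fill::zeros);
  arma::vec gbv(Cout, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const double *gyp = REAL(gy) + (size_t)HW * Cout * n;
    for (int cout = 0; cout < Cout; ++cout) {
      float *dst = GY.colptr(cout);
      const double *src = gyp + (size_t)HW * cout;
      double acc = 0;
      for (int p = 0; p < HW; ++p) { dst[p] = (float)src[p]; acc += src[p]; }
      gbv(cout) += acc;
    }
    im2col3(REAL(x) + (size_t)HW * Cin * n, H, W, Cin, K);
    gWt += K.t() * GY;
    if (!need_gx) continue;
    arma::fmat GX = GY * Wt.t(); // (HW x 9Cin)
    double *gxp = REAL(gx) + (size_t)HW * Cin * n;
    // col2im accumulate
    for (int cin = 0; cin < Cin; ++cin) {
      double *gxc = gxp + (size_t)HW * cin;
      for (int dx = -1; dx <= 1; ++dx) {
        for (int dy = -1; dy <= 1; ++dy) {
          const int r = cin * 9 + (dx + 1) * 3 + (dy + 1);
          const float *gcol = GX.colptr(r);
          for (int ix = 0; ix < W; ++ix) {
            const int sx = ix + dx;
            if (sx < 0 || sx >= W) continue;
            double *dst = gxc + (size_t)H * sx;
            const float *src = gcol + (size_t)H * ix;
            const int z0 = std::max(0, -dy), z1 = std::min(H, H - dy);
            for (int iz = z0; iz < z1; ++iz) dst[iz + dy] += (double)src[iz];
          }
        }
      }
    }
  }
  double *gwp = REAL(gw);
  for (int cout = 0; cout < Cout; ++cout)
    for (int cin = 0; cin < Cin; ++cin)
      for (int dx = 0; dx < 3; ++dx)
        for (int dy = 0; dy < 3; ++dy)
          gwp[dy + 3 * dx + 9 * cin + 9 * (size_t)Cin * cout] =
              (double)gWt(cin * 9 + dx * 3 + dy, cout);
  for (int cout = 0; cout < Cout; ++cout) gb[cout] = gbv(cout);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List nn_pool_fw(NumericVector x) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("pool: spatial dims must be even");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size());
  idx.attr("dim") = y.attr("dim");
  const double *xp = REAL(x);
  double *yp = REAL(y);
  int *ip = INTEGER(idx);
  const R_xlen_t CN = (R_xlen_t)C * N;
  for (R_xlen_t cn = 0; cn < CN; ++cn) {
    const double *xs = xp + (size_t)H * W * cn;
    double *ys = yp + (size_t)Ho * Wo * cn;
    int *is = ip + (size_t)Ho * Wo * cn;
    for (int ox = 0; ox < Wo; ++ox) {
      for (int oz = 0; oz < Ho; ++oz) {
        const int bz = 2 * oz, bx = 2 * ox;
        double best = xs[bz + (size_t)H * bx];
        int bi = 0;
        for (int k = 1; k < 4; ++k) {
          const int dz = k & 1, dx2 = k >> 1;
          const double v = xs[bz + dz + (size_t)H * (bx + dx2)];
          if (v > best) { best = v; bi = k; }
        }
        ys[oz + (size_t)Ho * ox] = best;
        is[oz + (size_t)Ho * ox] = bi;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector nn_pool_bw(NumericVector gy, IntegerVector idx, int H, int W) {
  IntegerVector d = dims4(gy);
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double *gp = REAL(gy);
  const int *ip = INTEGER(idx);
  double *op = REAL(gx);
  const R_xlen_t CN = (R_xlen_t)C * N;
  for (R_xlen_t cn = 0; cn < CN; ++cn) {
    const double *gs = gp + (size_t)Ho * Wo * cn;
    const int *is = ip + (size_t)Ho * Wo * cn;
    double *os = op + (size_t)H * W * cn;
    for (int ox = 0; ox < Wo; ++ox)
      for (int oz = 0; oz < Ho; ++oz) {
        const int k = is[oz + (size_t)Ho * ox];
        os[2 * oz + (k & 1) + (size_t)H * (2 * ox + (k >> 1))] +=
            gs[oz + (size_t)Ho * ox];
      }
  }
  return gx;
}

// weight matrix Cin x (4*Cout) from w(2,2,Cin,Cout); k = di + 2*dj.
static arma::fmat wmat_up(const NumericVector &w, int Cin, int Cout) {
  arma::fmat Wm(Cin, 4 * Cout);
  const double *wp = REAL(w);
  for (int cout = 0; cout < Cout; ++cout)
    for (int cin = 0; cin < Cin; ++cin)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di)
          Wm(cin, di + 2 * dj + 4 * cout) =
              (float)wp[di + 2 * dj + 4 * cin + 4 * (size_t)Cin * cout];
  return Wm;
}

// [[Rcpp::export]]
NumericVector nn_upconv_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], Cin = d[2], N = d[3];
  IntegerVector wd = w.attr("dim");
  const int Cout = wd[3];
  NumericVector y((R_xlen_t)4 * H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(2 * H, 2 * W, Cout, N);
  arma::fmat Wm = wmat_up(w, Cin, Cout);
  const double *bp = REAL(b);
  const int HW = H * W;
  arma::fmat X(HW, Cin);
  for (int n = 0; n < N; ++n) {
    const double *xp = REAL(x) + (size_t)HW * Cin * n;
    for (int cin = 0; cin < Cin; ++cin) {
      float *dst = X.colptr(cin);
      const double *src = xp + (size_t)HW * cin;
      for (int p = 0; p < HW; ++p) dst[p] = (float)src[p];
    }
    arma::fmat Y = X * Wm; // (HW x 4Cout)
    double *yp = REAL(y) + (size_t)4 * HW * Cout * n;
    for (int cout = 0; cout < Cout; ++cout) {
      double *yc = yp + (size_t)4 * HW * cout;
      const double bc = bp[cout];
      for (int k = 0; k < 4; ++k) {
        const int di = k & 1, dj = k >> 1;
        const float *src = Y.colptr(k + 4 * cout);
        for (int ix = 0; ix < W; ++ix) {
          double *dst = yc + (size_t)2 * H * (2 * ix + dj) + di;
          const float *s = src + (size_t)H * ix;
          for (int iz = 0; iz < H; ++iz) dst[2 * iz] = (double)s[iz] + bc;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List nn_upconv_bw(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], Cin = d[2], N = d[3];
  IntegerVector wd = w.attr("dim");
  const int Cout = wd[3];
  NumericVector gx(x.size());
  gx.attr("dim") = d;
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(Cout);
  arma::fmat Wm = wmat_up(w, Cin, Cout);
  arma::fmat gWm(Cin, 4 * Cout, arma::fill::zeros);
  arma::vec gbv(Cout, arma::fill::zeros);
  const int HW = H * W;
  arma::fmat GY(HW, 4 * Cout);
  arma::fmat X(HW, Cin);
  for (int n = 0; n < N; ++n) {
    const double *gyp = REAL(gy) + (size_t)4 * HW * Cout * n;
    for (int cout = 0; cout < Cout; ++cout) {
      const double *gc = gyp + (size_t)4 * HW * cout;
      double acc = 0;
      for (int k = 0; k < 4; ++k) {
        const int di = k & 1, dj = k >> 1;
        float *dst = GY.colptr(k + 4 * cout);
        for (int ix = 0; ix < W; ++ix) {
          const double *s = gc + (size_t)2 * H * (2 * ix + dj) + di;
          float *dd = dst + (size_t)H * ix;
          for (int iz = 0; iz < H; ++iz) { dd[iz] = (float)s[2 * iz]; acc += s[2 * iz]; }
        }
      }
      gbv(cout) += acc;
    }
    const double *xp = REAL(x) + (size_t)HW * Cin * n;
    for (int cin = 0; cin < Cin; ++cin) {
      float *dst = X.colptr(cin);
      const double *src = xp + (size_t)HW * cin;
      for (int p = 0; p < HW; ++p) dst[p] = (float)src[p];
    }
    gWm += X.t() * GY;
    arma::fmat GX = GY * Wm.t(); // (HW x Cin)
    double *gxp = REAL(gx) + (size_t)HW * Cin * n;
    for (int cin = 0; cin < Cin; ++cin) {
      const float *src = GX.colptr(cin);
      double *dst = gxp + (size_t)HW * cin;
      for (int p = 0; p < HW; ++p) dst[p] = (double)src[p];
    }
  }
  double *gwp = REAL(gw);
  for (int cout = 0; cout < Cout; ++cout)
    for (int cin = 0; cin < Cin; ++cin)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di)
          gwp[di + 2 * dj + 4 * cin + 4 * (size_t)Cin * cout] =
              (double)gWm(cin, di + 2 * dj + 4 * cout);
  for (int cout = 0; cout < Cout; ++cout) gb[cout] = gbv(cout);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Batch normalization over (H, W, N) per channel, training mode,
// with an optionally fused rectified-linear activation.
// [[Rcpp::export]]
List nn_bn_fw(NumericVector x, NumericVector gamma, NumericVector beta,
              double eps, bool relu = false) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const R_xlen_t HW = (R_xlen_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = d;
  NumericVector mean(C), invstd(C);
  const double *xp = REAL(x);
  double *yp = REAL(y);
  const double M = (double)HW * N;
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double *xs = xp + HW * (c + (R_xlen_t)C * n);
      for (R_xlen_t p = 0; p < HW; ++p) { s += xs[p]; s2 += xs[p] * xs[p]; }
    }
    const double mu = s / M;
    double var = s2 / M - mu * mu;
    if (var < 0) var = 0;
    const double is = 1.0 / std::sqrt(var + eps);
    mean[c] = mu;
    invstd[c] = is;
    const double g = gamma[c] * is, bb = beta[c] - gamma[c] * is * mu;
    for (int n = 0; n < N; ++n) {
      const double *xs = xp + HW * (c + (R_xlen_t)C * n);
      double *ys = yp + HW * (c + (R_xlen_t)C * n);
      if (relu) {
        for (R_xlen_t p = 0; p < HW; ++p) {
          const double v = g * xs[p] + bb;
          ys[p] = v > 0 ? v : 0;
        }
      } else {
        for (R_xlen_t p = 0; p < HW; ++p) ys[p] = g * xs[p] + bb;
      }
    }
  }
  return List::create(_["y"] = y, _["mean"] = mean, _["invstd"] = invstd);
}

// Backward through batch-norm with the ReLU mask (y > 0, where y is
// the cached post-activation output) applied to gy on the fly.
// [[Rcpp::export]]
List nn_bn_bw(NumericVector x, NumericVector gy, NumericVector gamma,
              NumericVector mean, NumericVector invstd,
              Nullable<NumericVector> relu_y = R_NilValue) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const R_xlen_t HW = (R_xlen_t)H * W;
  NumericVector gx(x.size());
  gx.attr("dim") = d;
  NumericVector ggamma(C), gbeta(C);
  const double *xp = REAL(x), *gp = REAL(gy);
  const double *yp = relu_y.isNotNull() ?
      REAL(NumericVector(relu_y)) : (const double *)0;
  double *op = REAL(gx);
  const double M = (double)HW * N;
  for (int c = 0; c < C; ++c) {
    const double mu = mean[c], is = invstd[c], g = gamma[c];
    double sg = 0, sgx = 0;
    for (int n = 0; n < N; ++n) {
      const R_xlen_t off = HW * (c + (R_xlen_t)C * n);
      const double *xs = xp + off;
      const double *gs = gp + off;
      const double *ys = yp ? yp + off : 0;
      for (R_xlen_t p = 0; p < HW; ++p) {
        const double gv = ys ? (ys[p] > 0 ? gs[p] : 0.0) : gs[p];
        sg += gv;
        sgx += gv * (xs[p] - mu) * is;
      }
    }
    gbeta[c] = sg;
    ggamma[c] = sgx;
    const double a = g * is / M;
    for (int n = 0; n < N; ++n) {
      const R_xlen_t off = HW * (c + (R_xlen_t)C * n);
      const double *xs = xp + off;
      const double *gs = gp + off;
      const double *ys = yp ? yp + off : 0;
      double *os = op + off;
      for (R_xlen_t p = 0; p < HW; ++p) {
        const double gv = ys ? (ys[p] > 0 ? gs[p] : 0.0) : gs[p];
        const double xh = (xs[p] - mu) * is;
        os[p] = a * (M * gv - sg - xh * sgx);
      }
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma,
                      _["gbeta"] = gbeta);
}

// Inference-mode normalization with fixed statistics.
// [[Rcpp::export]]
NumericVector nn_bn_apply(NumericVector x, NumericVector gamma,
                          NumericVector beta, NumericVector mean,
                          NumericVector var, double eps) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const R_xlen_t HW = (R_xlen_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = d;
  const double *xp = REAL(x);
  double *yp = REAL(y);
  for (int c = 0; c < C; ++c) {
    const double is = 1.0 / std::sqrt(var[c] + eps);
    const double g = gamma[c] * is, bb = beta[c] - gamma[c] * is * mean[c];
    for (int n = 0; n < N; ++n) {
      const double *xs = xp + HW * (c + (R_xlen_t)C * n);
      double *ys = yp + HW * (c + (R_xlen_t)C * n);
      for (R_xlen_t p = 0; p < HW; ++p) ys[p] = g * xs[p] + bb;
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector nn_relu_fw(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double *xp = REAL(x);
  double *yp = REAL(y);
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) yp[i] = xp[i] > 0 ? xp[i] : 0;
  return y;
}

// [[Rcpp::export]]
NumericVector nn_relu_bw(NumericVector y, NumericVector gy) {
  NumericVector gx(y.size());
  gx.attr("dim") = y.attr("dim");
  const double *yp = REAL(y), *gp = REAL(gy);
  double *op = REAL(gx);
  const R_xlen_t n = y.size();
  for (R_xlen_t i = 0; i < n; ++i) op[i] = yp[i] > 0 ? gp[i] : 0;
  return gx;
}

// Channel concatenation / split for the skip connections.
// [[Rcpp::export]]
NumericVector nn_cat_channels(NumericVector a, NumericVector b) {
  IntegerVector da = dims4(a), db = dims4(b);
  const int H = da[0], W = da[1], Ca = da[2], Cb = db[2], N = da[3];
  if (db[0] != H || db[1] != W || db[3] != N) stop("concat: shape mismatch");
  NumericVector y((R_xlen_t)H * W * (Ca + Cb) * N);
  y.attr("dim") = IntegerVector::create(H, W, Ca + Cb, N);
  const size_t HW = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    std::memcpy(REAL(y) + HW * (Ca + Cb) * n,
                REAL(a) + HW * Ca * n, sizeof(double) * HW * Ca);
    std::memcpy(REAL(y) + HW * (Ca + Cb) * n + HW * Ca,
                REAL(b) + HW * Cb * n, sizeof(double) * HW * Cb);
  }
  return y;
}

// [[Rcpp::export]]
List nn_split_channels(NumericVector y, int Ca) {
  IntegerVector d = dims4(y);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Cb = C - Ca;
  NumericVector a((R_xlen_t)H * W * Ca * N), b((R_xlen_t)H * W * Cb * N);
  a.attr("dim") = IntegerVector::create(H, W, Ca, N);
  b.attr("dim") = IntegerVector::create(H, W, Cb, N);
  const size_t HW = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    std::memcpy(REAL(a) + HW * Ca * n, REAL(y) + HW * C * n,
                sizeof(double) * HW * Ca);
    std::memcpy(REAL(b) + HW * Cb * n, REAL(y) + HW * C * n + HW * Ca,
                sizeof(double) * HW * Cb);
  }
  return List::create(_["a"] = a, _["b"] = b);
}
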