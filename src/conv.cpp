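// Convolution kernels for the two-branch CNN: same-padding, stride-1
// 2-D convolution via im2col + BLAS matrix products, plus the exact
// gradients needed for backpropagation. Layouts follow R column-major
// arrays: signals are (H, W, C, N), weights arrive as a K x Cout matrix
// with K = kh*kw*Cin and row order (ki fastest, then kj, then cin).
// The patch matrix is held transposed, (H*W) x K, so that both the fill
// and the matrix products touch contiguous memory.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void im2col_t(const double* x, int H, int W, int C,
                     int kh, int kw, arma::mat& colT) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * HW;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        double* dst = colT.colptr(r);
        for (int w = 0; w < W; ++w) {
          const int ws = w + kj - pw;
          double* d = dst + (size_t)w * H;
          if (ws < 0 || ws >= W) {
            std::fill(d, d + H, 0.0);
            continue;
          }
          const double* src = xc + (size_t)ws * H;
          const int lo = std::max(0, ph - ki);          // h with hs >= 0
          const int hi = std::min(H, H + ph - ki);      // h with hs < H
          if (lo > 0) std::fill(d, d + lo, 0.0);
          if (hi > lo) std::copy(src + lo + ki - ph, src + hi + ki - ph, d + lo);
          if (hi < H) std::fill(d + hi, d + H, 0.0);
        }
      }
    }
  }
}

static void col2im_t_acc(const arma::mat& colT, int H, int W, int C,
                         int kh, int kw, double* dx) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)c * HW;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        const double* src0 = colT.colptr(r);
        for (int w = 0; w < W; ++w) {
          const int ws = w + kj - pw;
          if (ws < 0 || ws >= W) continue;
          const double* s = src0 + (size_t)w * H;
          double* d = xc + (size_t)ws * H + (ki - ph);
          const int lo = std::max(0, ph - ki);
          const int hi = std::min(H, H + ph - ki);
          for (int h = lo; h < hi; ++h) d[h] += s[h];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, IntegerVector dims,
                                 NumericMatrix wmat, NumericVector bias,
                                 int kh, int kw, bool relu = false) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int K = kh * kw * C, Cout = wmat.ncol();
  if (wmat.nrow() != K) stop("weight matrix rows do not match kh*kw*Cin");
  NumericVector out((size_t)H * W * Cout * N);
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat Wm(wmat.begin(), K, Cout, false);
  arma::mat colT((size_t)H * W, K);
  arma::rowvec b(bias.begin(), Cout);
  for (int n = 0; n < N; ++n) {
    im2col_t(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, colT);
    arma::mat o(out.begin() + (size_t)n * H * W * Cout,
                (size_t)H * W, Cout, false, true);
    o = colT * Wm;                       // (H*W) x Cout
    o.each_row() += b;
    if (relu) o.for_each([](double& v) { if (v < 0) v = 0; });
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, IntegerVector dims,
                         NumericMatrix wmat, NumericVector dout,
                         int kh, int kw) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int K = kh * kw * C, Cout = wmat.ncol();
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::mat Wm(wmat.begin(), K, Cout, false);
  arma::mat dW(K, Cout, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);
  arma::mat colT((size_t)H * W, K);
  arma::mat dcolT((size_t)H * W, K);
  for (int n = 0; n < N; ++n) {
    im2col_t(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, colT);
    arma::mat dO(dout.begin() + (size_t)n * H * W * Cout,
                 (size_t)H * W, Cout, false);
    dW += colT.t() * dO;
    db += arma::sum(dO, 0);
    dcolT = dO * Wm.t();                 // (H*W) x K
    col2im_t_acc(dcolT, H, W, C, kh, kw, dx.begin() + (size_t)n * H * W * C);
  }
  return List::create(_["dx"] = dx,
                      _["dw"] = wrap(dW),
                      _["db"] = wrap(arma::vec(db.t())));
}

// Centered running median with reflect padding; even window widths are
// allowed (median of an even count is the mean of the two middle order
// statistics). Window for even w covers w/2 samples left, w/2 - 1 right.
// [[Rcpp::export]]
NumericVector cpp_running_median(NumericVector x, int w) {
  const int n = x.size();
  if (w < 1) stop("window must be >= 1");
  if (w > n) stop("window longer than signal");
  NumericVector out(n);
  const int lh = w / 2, rh = w - 1 - lh;
  std::vector<double> buf(w);
  for (int i = 0; i < n; ++i) {
    for (int j = -lh; j <= rh; ++j) {
      int k = i + j;
      if (k < 0) k = -k - 1;               // reflect: x[-1] -> x[0]
      if (k >= n) k = 2 * n - 1 - k;       // reflect at the right edge
      buf[j + lh] = x[k];
    }
    const int m = w / 2;
    std::nth_element(buf.begin(), buf.begin() + m, buf.end());
    double med = buf[m];
    if (w % 2 == 0) {
      std::nth_element(buf.begin(), buf.begin() + m - 1, buf.begin() + m);
      med = 0.5 * (med + buf[m - 1]);
    }
    out[i] = med;
  }
  return out;
}

// ---- channel-broadcast helpers (avoid large R temporaries) ----------------
// x has dims (H, W, C, N); scale/shift are C x N matrices broadcast over
// the spatial extent.

// [[Rcpp::export]]
NumericVector cpp_relu(NumericVector x) {
  NumericVector out = clone(x);
  for (double& v : out) if (v < 0) v = 0;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_relu_backward(NumericVector dout, NumericVector act) {
  NumericVector out = clone(dout);
  const R_xlen_t n = out.size();
  for (R_xlen_t i = 0; i < n; ++i) if (act[i] <= 0) out[i] = 0;
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_channel_means(NumericVector x, IntegerVector dims) {
  const size_t HW = (size_t)dims[0] * dims[1];
  const int C = dims[2], N = dims[3];
  NumericMatrix out(C, N);
  const double* p = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double s = 0;
      for (size_t i = 0; i < HW; ++i) s += *p++;
      out(c, n) = s / HW;
    }
  return out;
}

// per-(channel, sample) inner product over the spatial extent
// [[Rcpp::export]]
NumericMatrix cpp_channel_dot(NumericVector x, NumericVector y,
                              IntegerVector dims) {
  const size_t HW = (size_t)dims[0] * dims[1];
  const int C = dims[2], N = dims[3];
  NumericMatrix out(C, N);
  const double* px = x.begin();
  const double* py = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double s = 0;
      for (size_t i = 0; i < HW; ++i) s += *px++ * *py++;
      out(c, n) = s;
    }
  return out;
}

// out = x * scale[c,n] + shift[c,n], broadcast spatially
// [[Rcpp::export]]
NumericVector cpp_chan_scale_shift(NumericVector x, IntegerVector dims,
                                   NumericMatrix scale, NumericMatrix shift) {
  const size_t HW = (size_t)dims[0] * dims[1];
  const int C = dims[2], N = dims[3];
  NumericVector out(x.size());
  out.attr("dim") = dims;
  const double* p = x.begin();
  double* q = out.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double a = scale(c, n), b = shift(c, n);
      for (size_t i = 0; i < HW; ++i) *q++ = *p++ * a + b;
    }
  return out;
}

// per-slice product A * X * B over the C*N slices of an (H, W, C, N)
// array; A is (Ho x H), B is (W x Wo). Used for the bicubic feature-map
// resize (forward and, with transposed weights, backward).
// [[Rcpp::export]]
NumericVector cpp_slice_gemm(NumericVector x, IntegerVector dims,
                             NumericMatrix A, NumericMatrix B) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int Ho = A.nrow(), Wo = B.ncol();
  if (A.ncol() != H || B.nrow() != W) stop("resize weight shape mismatch");
  NumericVector out((size_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  arma::mat Am(A.begin(), Ho, H, false);
  arma::mat Bm(B.begin(), W, Wo, false);
  const size_t nsl = (size_t)C * N;
  for (size_t k = 0; k < nsl; ++k) {
    arma::mat X(x.begin() + k * H * W, H, W, false);
    arma::mat O(out.begin() + k * Ho * Wo, Ho, Wo, false, true);
    O = Am * X * Bm;
  }
  return out;
}

// ---- single-precision convolution path ------------------------------------
// Identical algorithm in float32: inputs/outputs stay double at the R
// boundary, arithmetic and the patch matrix are float. Used for training
// speed; the double path remains the reference for gradient checks.

static void im2col_t_f(const double* x, int H, int W, int C,
                       int kh, int kw, arma::fmat& colT) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * HW;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        float* dst = colT.colptr(r);
        for (int w = 0; w < W; ++w) {
          const int ws = w + kj - pw;
          float* d = dst + (size_t)w * H;
          if (ws < 0 || ws >= W) {
            std::fill(d, d + H, 0.0f);
            continue;
          }
          const double* src = xc + (size_t)ws * H + (ki - ph);
          const int lo = std::max(0, ph - ki);
          const int hi = std::min(H, H + ph - ki);
          if (lo > 0) std::fill(d, d + lo, 0.0f);
          for (int h = lo; h < hi; ++h) d[h] = (float)src[h];
          if (hi < H) std::fill(d + hi, d + H, 0.0f);
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward_f32(NumericVector x, IntegerVector dims,
                                     NumericMatrix wmat, NumericVector bias,
                                     int kh, int kw, bool relu = false) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int K = kh * kw * C, Cout = wmat.ncol();
  if (wmat.nrow() != K) stop("weight matrix rows do not match kh*kw*Cin");
  NumericVector out((size_t)H * W * Cout * N);
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::fmat Wm = arma::conv_to<arma::fmat>::from(
    arma::mat(wmat.begin(), K, Cout, false));
  arma::frowvec b = arma::conv_to<arma::frowvec>::from(
    arma::vec(bias.begin(), Cout, false));
  arma::fmat colT((size_t)H * W, K);
  arma::fmat o((size_t)H * W, Cout);
  for (int n = 0; n < N; ++n) {
    im2col_t_f(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, colT);
    o = colT * Wm;
    o.each_row() += b;
    if (relu) o.for_each([](float& v) { if (v < 0) v = 0; });
    double* q = out.begin() + (size_t)n * H * W * Cout;
    const float* p = o.memptr();
    for (size_t i = 0; i < (size_t)H * W * Cout; ++i) q[i] = p[i];
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_backward_f32(NumericVector x, IntegerVector dims,
                             NumericMatrix wmat, NumericVector dout,
                             int kh, int kw) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int K = kh * kw * C, Cout = wmat.ncol();
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::fmat Wm = arma::conv_to<arma::fmat>::from(
    arma::mat(wmat.begin(), K, Cout, false));
  arma::fmat dW(K, Cout, arma::fill::zeros);
  arma::frowvec db(Cout, arma::fill::zeros);
  arma::fmat colT((size_t)H * W, K);
  arma::fmat dcolT((size_t)H * W, K);
  arma::fmat dO((size_t)H * W, Cout);
  for (int n = 0; n < N; ++n) {
    im2col_t_f(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, colT);
    const double* ds = dout.begin() + (size_t)n * H * W * Cout;
    float* dp = dO.memptr();
    for (size_t i = 0; i < (size_t)H * W * Cout; ++i) dp[i] = (float)ds[i];
    dW += colT.t() * dO;
    db += arma::sum(dO, 0);
    dcolT = dO * Wm.t();
    // accumulate into dx (double) via a float staging view
    {
      const int phh = (kh - 1) / 2, pww = (kw - 1) / 2;
      double* dxn = dx.begin() + (size_t)n * H * W * C;
      for (int c = 0; c < C; ++c) {
        double* xc = dxn + (size_t)c * H * W;
        for (int kj = 0; kj < kw; ++kj) {
          for (int ki = 0; ki < kh; ++ki) {
            const int r = ki + kh * (kj + kw * c);
            const float* src0 = dcolT.colptr(r);
            for (int w = 0; w < W; ++w) {
              const int ws = w + kj - pww;
              if (ws < 0 || ws >= W) continue;
              const float* s = src0 + (size_t)w * H;
              double* d = xc + (size_t)ws * H + (ki - phh);
              const int lo = std::max(0, phh - ki);
              const int hi = std::min(H, H + phh - ki);
              for (int h = lo; h < hi; ++h) d[h] += s[h];
            }
          }
        }
      }
    }
  }
  arma::mat dWd = arma::conv_to<arma::mat>::from(dW);
  arma::vec dbd = arma::conv_to<arma::vec>::from(db.t());
  return List::create(_["dx"] = dx, _["dw"] = wrap(dWd), _["db"] = wrap(dbd));
}
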