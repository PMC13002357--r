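#include <Rcpp.h>
using namespace Rcpp;

// Fused elementwise layers. Dropout draws its mask from R's RNG so training
// stays reproducible under set.seed().

// [[Rcpp::export]]
NumericVector nn_relu_forward(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double *p = x.begin();
  double *q = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) q[i] = p[i] > 0 ? p[i] : 0.0;
  return y;
}

// gradient masked by the forward output (y > 0 <=> x > 0)
// [[Rcpp::export]]
NumericVector nn_relu_backward(NumericVector gy, NumericVector y) {
  NumericVector gx(gy.size());
  gx.attr("dim") = gy.attr("dim");
  const double *g = gy.begin(), *p = y.begin();
  double *q = gx.begin();
  for (R_xlen_t i = 0; i < gy.size(); ++i) q[i] = p[i] > 0 ? g[i] : 0.0;
  return gx;
}

// [[Rcpp::export]]
List nn_dropout_forward(NumericVector x, double rate) {
  R_xlen_t n = x.size();
  NumericVector y(n), mask(n);
  y.attr("dim") = x.attr("dim");
  double scale = 1.0 / (1.0 - rate);
  const double *p = x.begin();
  double *q = y.begin(), *m = mask.begin();
  GetRNGstate();
  for (R_xlen_t i = 0; i < n; ++i) {
    double keep = unif_rand() >= rate ? scale : 0.0;
    m[i] = keep;
    q[i] = p[i] * keep;
  }
  PutRNGstate();
  return List::create(_["y"] = y, _["mask"] = mask);
}

// [[Rcpp::export]]
NumericVector nn_mask_mul(NumericVector gy, NumericVector mask) {
  NumericVector gx(gy.size());
  gx.attr("dim") = gy.attr("dim");
  const double *g = gy.begin(), *m = mask.begin();
  double *q = gx.begin();
  for (R_xlen_t i = 0; i < gy.size(); ++i) q[i] = g[i] * m[i];
  return gx;
}

// 2x nearest-neighbor upsampling of (H, W, C, N)
// [[Rcpp::export]]
NumericVector nn_upsample2_forward(NumericVector x) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  NumericVector y((R_xlen_t)4 * H * W * C * N);
  y.attr("dim") = IntegerVector::create(2 * H, 2 * W, C, N);
  const double *p = x.begin();
  double *q = y.begin();
  for (int cn = 0; cn < C * N; ++cn) {
    const double *src = p + (size_t)cn * H * W;
    double *dst = q + (size_t)cn * 4 * H * W;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        double v = src[(size_t)w * H + h];
        size_t b = (size_t)(2 * w) * 2 * H + 2 * h;
        dst[b] = v; dst[b + 1] = v;
        dst[b + 2 * H] = v; dst[b + 2 * H + 1] = v;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector nn_upsample2_backward(NumericVector gy) {
  IntegerVector d = gy.attr("dim");
  int H2 = d[0], W2 = d[1], C = d[2], N = d[3];
  int H = H2 / 2, W = W2 / 2;
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double *g = gy.begin();
  double *q = gx.begin();
  for (int cn = 0; cn < C * N; ++cn) {
    const double *src = g + (size_t)cn * H2 * W2;
    double *dst = q + (size_t)cn * H * W;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        size_t b = (size_t)(2 * w) * H2 + 2 * h;
        dst[(size_t)w * H + h] = src[b] + src[b + 1] + src[b + H2] + src[b + H2 + 1];
      }
    }
  }
  return gx;
}

// channel-wise concatenation of two (H, W, *, N) arrays
// [[Rcpp::export]]
NumericVector nn_concat_ch(NumericVector a, NumericVector b) {
  IntegerVector da = a.attr("dim"), db = b.attr("dim");
  int H = da[0], W = da[1], Ca = da[2], Cb = db[2], N = da[3];
  size_t HW = (size_t)H * W;
  NumericVector y(HW * (Ca + Cb) * N);
  y.attr("dim") = IntegerVector::create(H, W, Ca + Cb, N);
  for (int n = 0; n < N; ++n) {
    std::copy(a.begin() + n * HW * Ca, a.begin() + (n + 1) * HW * Ca,
              y.begin() + (size_t)n * HW * (Ca + Cb));
    std::copy(b.begin() + n * HW * Cb, b.begin() + (n + 1) * HW * Cb,
              y.begin() + (size_t)n * HW * (Ca + Cb) + HW * Ca);
  }
  return y;
}

// [[Rcpp::export]]
List nn_split_ch(NumericVector g, int Ca) {
  IntegerVector d = g.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Cb = C - Ca;
  size_t HW = (size_t)H * W;
  NumericVector a(HW * Ca * N), b(HW * Cb * N);
  a.attr("dim") = IntegerVector::create(H, W, Ca, N);
  b.attr("dim") = IntegerVector::create(H, W, Cb, N);
  for (int n = 0; n < N; ++n) {
    std::copy(g.begin() + (size_t)n * HW * C,
              g.begin() + (size_t)n * HW * C + HW * Ca,
              a.begin() + (size_t)n * HW * Ca);
    std::copy(g.begin() + (size_t)n * HW * C + HW * Ca,
              g.begin() + (size_t)(n + 1) * HW * C,
              b.begin() + (size_t)n * HW * Cb);
  }
  return List::create(_["a"] = a, _["b"] = b);
}
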