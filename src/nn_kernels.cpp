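#include <Rcpp.h>
using namespace Rcpp;

// Tensors are R arrays with dim (H, W, C, N), column-major.
// im2col lays out one row per output position (h fastest, then w, then n)
// and one column per (ki, kj, c) kernel tap, so that a 'same' convolution
// is cols %*% Wmat with Wmat of dim (k*k*C) x Cout.

// [[Rcpp::export]]
NumericMatrix nn_im2col(NumericVector x, int k) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int pad = (k - 1) / 2;
  R_xlen_t nrow = (R_xlen_t)H * W * N;
  int ncol = k * k * C;
  NumericMatrix out(nrow, ncol);
  const double *px = x.begin();
  double *po = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        int col = ki + k * (kj + k * c);
        double *dst = po + (R_xlen_t)col * nrow;
        for (int n = 0; n < N; ++n) {
          const double *src = px + ((R_xlen_t)n * C + c) * H * W;
          double *drow = dst + (R_xlen_t)n * H * W;
          for (int w = 0; w < W; ++w) {
            int sw = w + kj - pad;
            if (sw < 0 || sw >= W) {
              // zero padding: leave zeros
              continue;
            }
            const double *scol = src + (R_xlen_t)sw * H;
            double *dcol = drow + (R_xlen_t)w * H;
            int h0 = std::max(0, pad - ki);
            int h1 = std::min(H, H + pad - ki);
            for (int h = h0; h < h1; ++h)
              dcol[h] = scol[h + ki - pad];
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of nn_im2col: scatter-add columns back into an (H,W,C,N) array.
// [[Rcpp::export]]
NumericVector nn_col2im(NumericMatrix cols, int H, int W, int C, int N, int k) {
  int pad = (k - 1) / 2;
  R_xlen_t nrow = (R_xlen_t)H * W * N;
  NumericVector out((R_xlen_t)H * W * C * N);
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  const double *pc = cols.begin();
  double *po = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        int col = ki + k * (kj + k * c);
        const double *src = pc + (R_xlen_t)col * nrow;
        for (int n = 0; n < N; ++n) {
          double *dst = po + ((R_xlen_t)n * C + c) * H * W;
          const double *srow = src + (R_xlen_t)n * H * W;
          for (int w = 0; w < W; ++w) {
            int sw = w + kj - pad;
            if (sw < 0 || sw >= W) continue;
            double *dcol = dst + (R_xlen_t)sw * H;
            const double *scol = srow + (R_xlen_t)w * H;
            int h0 = std::max(0, pad - ki);
            int h1 = std::min(H, H + pad - ki);
            for (int h = h0; h < h1; ++h)
              dcol[h + ki - pad] += scol[h];
          }
        }
      }
    }
  }
  return out;
}

// 2x2 max pooling with stride 2. Returns pooled values and the linear
// (1-based) argmax indices into the input array, for the backward pass.
// [[Rcpp::export]]
List nn_maxpool(NumericVector x) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double *px = x.begin();
  double *py = y.begin();
  int *pi = idx.begin();
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      R_xlen_t base = ((R_xlen_t)n * C + c) * H * W;
      for (int w = 0; w < Wo; ++w) {
        for (int h = 0; h < Ho; ++h) {
          R_xlen_t i00 = base + (R_xlen_t)(2 * w) * H + 2 * h;
          R_xlen_t best = i00;
          double v = px[i00];
          if (px[i00 + 1] > v) { v = px[i00 + 1]; best = i00 + 1; }
          if (px[i00 + H] > v) { v = px[i00 + H]; best = i00 + H; }
          if (px[i00 + H + 1] > v) { v = px[i00 + H + 1]; best = i00 + H + 1; }
          py[o] = v;
          pi[o] = (int)(best + 1);
          ++o;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector nn_maxpool_backward(NumericVector gy, IntegerVector idx,
                                  int H, int W, int C, int N) {
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double *pg = gy.begin();
  const int *pi = idx.begin();
  double *po = gx.begin();
  R_xlen_t n = gy.size();
  for (R_xlen_t i = 0; i < n; ++i) po[pi[i] - 1] += pg[i];
  return gx;
}
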