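#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

// Per-sample im2col + BLAS dgemm convolution (stride 1, 'same' zero padding).
// Processing one sample at a time keeps the column buffer cache-resident and
// writes the output directly in (H, W, Cout, N) layout, avoiding large
// temporaries on the R side.

static void im2col_one(const double *x, double *cols, int H, int W, int C, int k) {
  int pad = (k - 1) / 2;
  int HW = H * W;
  for (int c = 0; c < C; ++c) {
    const double *src = x + (size_t)c * HW;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        double *dst = cols + ((size_t)(ki + k * (kj + k * c))) * HW;
        for (int w = 0; w < W; ++w) {
          int sw = w + kj - pad;
          double *dcol = dst + (size_t)w * H;
          if (sw < 0 || sw >= W) {
            std::fill(dcol, dcol + H, 0.0);
            continue;
          }
          const double *scol = src + (size_t)sw * H;
          int h0 = std::max(0, pad - ki);
          int h1 = std::min(H, H + pad - ki);
          for (int h = 0; h < h0; ++h) dcol[h] = 0.0;
          for (int h = h0; h < h1; ++h) dcol[h] = scol[h + ki - pad];
          for (int h = h1; h < H; ++h) dcol[h] = 0.0;
        }
      }
    }
  }
}

static void col2im_one(const double *cols, double *gx, int H, int W, int C, int k) {
  int pad = (k - 1) / 2;
  int HW = H * W;
  for (int c = 0; c < C; ++c) {
    double *dst = gx + (size_t)c * HW;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const double *src = cols + ((size_t)(ki + k * (kj + k * c))) * HW;
        for (int w = 0; w < W; ++w) {
          int sw = w + kj - pad;
          if (sw < 0 || sw >= W) continue;
          double *dcol = dst + (size_t)sw * H;
          const double *scol = src + (size_t)w * H;
          int h0 = std::max(0, pad - ki);
          int h1 = std::min(H, H + pad - ki);
          for (int h = h0; h < h1; ++h) dcol[h + ki - pad] += scol[h];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector nn_conv_forward(NumericVector x, NumericMatrix Wmat,
                              NumericVector bias, int k) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int kk = k * k * C, Cout = Wmat.ncol();
  int HW = H * W;
  NumericVector y((size_t)HW * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  std::vector<double> cols((size_t)HW * kk);
  const double one = 1.0, zero = 0.0;
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (size_t)n * HW * C, cols.data(), H, W, C, k);
    double *out = y.begin() + (size_t)n * HW * Cout;
    F77_CALL(dgemm)("N", "N", &HW, &Cout, &kk, &one, cols.data(), &HW,
                    Wmat.begin(), &kk, &zero, out, &HW FCONE FCONE);
    for (int c = 0; c < Cout; ++c) {
      double b = bias[c];
      double *oc = out + (size_t)c * HW;
      for (int i = 0; i < HW; ++i) oc[i] += b;
    }
  }
  return y;
}

// [[Rcpp::export]]
List nn_conv_backward(NumericVector x, NumericMatrix Wmat, NumericVector gy,
                      int k, bool need_gx = true) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int kk = k * k * C, Cout = Wmat.ncol();
  int HW = H * W;
  NumericVector gx(x.size());
  gx.attr("dim") = d;
  NumericMatrix gW(kk, Cout);
  NumericVector gb(Cout);
  std::vector<double> cols((size_t)HW * kk);
  std::vector<double> gcols((size_t)HW * kk);
  const double one = 1.0, zero = 0.0;
  for (int n = 0; n < N; ++n) {
    const double *xn = x.begin() + (size_t)n * HW * C;
    const double *gyn = gy.begin() + (size_t)n * HW * Cout;
    im2col_one(xn, cols.data(), H, W, C, k);
    // gW += cols^T %*% gy_n
    F77_CALL(dgemm)("T", "N", &kk, &Cout, &HW, &one, cols.data(), &HW,
                    const_cast<double *>(gyn), &HW, &one, gW.begin(), &kk
                    FCONE FCONE);
    if (need_gx) {
      // gcols = gy_n %*% W^T
      F77_CALL(dgemm)("N", "T", &HW, &kk, &Cout, &one,
                      const_cast<double *>(gyn), &HW, Wmat.begin(), &kk, &zero,
                      gcols.data(), &HW FCONE FCONE);
      col2im_one(gcols.data(), gx.begin() + (size_t)n * HW * C, H, W, C, k);
    }
    for (int c = 0; c < Cout; ++c) {
      const double *gc = gyn + (size_t)c * HW;
      double s = 0.0;
      for (int i = 0; i < HW; ++i) s += gc[i];
      gb[c] += s;
    }
  }
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}
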