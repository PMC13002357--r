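#include <Rcpp.h>
using namespace Rcpp;

// Batch normalization over (H, W, C, N) arrays: per-channel statistics
// across all pixels and samples, computed in single passes.

// [[Rcpp::export]]
List nn_bn_forward(NumericVector x, NumericVector gamma, NumericVector beta,
                   NumericVector mu, NumericVector var_, double eps,
                   bool compute_stats) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  size_t HW = (size_t)H * W;
  NumericVector mu_out(C), var_out(C);
  if (compute_stats) {
    for (int c = 0; c < C; ++c) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double *p = x.begin() + ((size_t)n * C + c) * HW;
        for (size_t i = 0; i < HW; ++i) { s += p[i]; s2 += p[i] * p[i]; }
      }
      double m = s / (HW * N);
      mu_out[c] = m;
      var_out[c] = s2 / (HW * N) - m * m;   // population variance
    }
  } else {
    mu_out = clone(mu);
    var_out = clone(var_);
  }
  NumericVector y(x.size()), xhat(x.size());
  y.attr("dim") = d;
  NumericVector inv_std(C);
  for (int c = 0; c < C; ++c) inv_std[c] = 1.0 / std::sqrt(var_out[c] + eps);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *p = x.begin() + ((size_t)n * C + c) * HW;
      double *py = y.begin() + ((size_t)n * C + c) * HW;
      double *ph = xhat.begin() + ((size_t)n * C + c) * HW;
      double m = mu_out[c], is = inv_std[c], g = gamma[c], b = beta[c];
      for (size_t i = 0; i < HW; ++i) {
        double h = (p[i] - m) * is;
        ph[i] = h;
        py[i] = g * h + b;
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mu"] = mu_out,
                      _["var"] = var_out, _["inv_std"] = inv_std);
}

// [[Rcpp::export]]
List nn_bn_backward(NumericVector gy, NumericVector xhat, NumericVector gamma,
                    NumericVector inv_std, IntegerVector dims, bool training) {
  int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  size_t HW = (size_t)H * W;
  double M = (double)HW * N;
  NumericVector ggamma(C), gbeta(C);
  for (int c = 0; c < C; ++c) {
    double sg = 0, sgh = 0;
    for (int n = 0; n < N; ++n) {
      size_t off = ((size_t)n * C + c) * HW;
      const double *g = gy.begin() + off;
      const double *h = xhat.begin() + off;
      for (size_t i = 0; i < HW; ++i) { sg += g[i]; sgh += g[i] * h[i]; }
    }
    gbeta[c] = sg;
    ggamma[c] = sgh;
  }
  NumericVector gx(gy.size());
  gx.attr("dim") = dims;
  for (int c = 0; c < C; ++c) {
    double ga = gamma[c], is = inv_std[c];
    double a = ga * gbeta[c] / M, b = ga * ggamma[c] / M;
    for (int n = 0; n < N; ++n) {
      size_t off = ((size_t)n * C + c) * HW;
      const double *g = gy.begin() + off;
      const double *h = xhat.begin() + off;
      double *o = gx.begin() + off;
      if (training) {
        for (size_t i = 0; i < HW; ++i)
          o[i] = (ga * g[i] - a - h[i] * b) * is;
      } else {
        for (size_t i = 0; i < HW; ++i)
          o[i] = ga * g[i] * is;
      }
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}
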