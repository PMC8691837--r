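// Hot loops of the 1D convolutional classifier: im2col gather/scatter,
// batch-normalization statistics and elementwise passes, and max pooling.
// Matrix products stay in R (BLAS); these kernels only move memory and
// do per-element arithmetic that is slow at the R level.

#include <Rcpp.h>
using namespace Rcpp;

// xp: [b, lp, cin] padded activations (as a numeric vector with dims);
// returns [b * l, cin * k] with tap-major column blocks.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector xp, int b, int lp, int cin,
                         int k) {
  const int l = lp - k + 1;
  NumericMatrix out(b * l, cin * k);
  const double *src = xp.begin();
  double *dst = out.begin();
  for (int u = 0; u < k; ++u) {
    for (int c = 0; c < cin; ++c) {
      double *col = dst + (size_t)(u * cin + c) * (b * l);
      const double *plane = src + (size_t)c * b * lp;
      for (int t = 0; t < l; ++t) {
        const double *seg = plane + (size_t)(t + u) * b;
        std::copy(seg, seg + b, col + (size_t)t * b);
      }
    }
  }
  return out;
}

// Scatter-add the tap blocks of dxc [b * l, cin * k] back onto the
// padded gradient [b, lp, cin].
// [[Rcpp::export]]
NumericVector cpp_col_fold(NumericMatrix dxc, int b, int lp, int cin,
                           int k) {
  const int l = lp - k + 1;
  NumericVector out((size_t)b * lp * cin);
  double *dst = out.begin();
  const double *src = dxc.begin();
  for (int u = 0; u < k; ++u) {
    for (int c = 0; c < cin; ++c) {
      const double *col = src + (size_t)(u * cin + c) * (b * l);
      double *plane = dst + (size_t)c * b * lp;
      for (int t = 0; t < l; ++t) {
        double *seg = plane + (size_t)(t + u) * b;
        const double *s = col + (size_t)t * b;
        for (int i = 0; i < b; ++i) seg[i] += s[i];
      }
    }
  }
  out.attr("dim") = IntegerVector::create(b, lp, cin);
  return out;
}

// Batch-norm forward on the flattened [n, c] view. Returns y and xhat;
// mu/istd are computed by the caller (training or running statistics).
// [[Rcpp::export]]
List cpp_bn_apply(NumericMatrix xf, NumericVector mu, NumericVector istd,
                  NumericVector gamma, NumericVector beta) {
  const int n = xf.nrow(), c = xf.ncol();
  NumericMatrix xhat(n, c), y(n, c);
  for (int j = 0; j < c; ++j) {
    const double m = mu[j], is = istd[j], g = gamma[j], bt = beta[j];
    const double *x = &xf(0, j);
    double *xh = &xhat(0, j);
    double *yy = &y(0, j);
    for (int i = 0; i < n; ++i) {
      const double v = (x[i] - m) * is;
      xh[i] = v;
      yy[i] = v * g + bt;
    }
  }
  return List::create(_["xhat"] = xhat, _["y"] = y);
}

// Per-column means and variances in one pass.
// [[Rcpp::export]]
List cpp_col_stats(NumericMatrix xf) {
  const int n = xf.nrow(), c = xf.ncol();
  NumericVector mu(c), va(c);
  for (int j = 0; j < c; ++j) {
    const double *x = &xf(0, j);
    double s = 0, s2 = 0;
    for (int i = 0; i < n; ++i) {
      s += x[i];
      s2 += x[i] * x[i];
    }
    const double m = s / n;
    mu[j] = m;
    double v = s2 / n - m * m;
    va[j] = v > 0 ? v : 0;
  }
  return List::create(_["mu"] = mu, _["va"] = va);
}

// Batch-norm backward on the flattened view.
// [[Rcpp::export]]
List cpp_bn_backward(NumericMatrix dyf, NumericMatrix xhat,
                     NumericVector istd, NumericVector gamma) {
  const int n = dyf.nrow(), c = dyf.ncol();
  NumericMatrix dx(n, c);
  NumericVector dgamma(c), dbeta(c);
  for (int j = 0; j < c; ++j) {
    const double *dy = &dyf(0, j);
    const double *xh = &xhat(0, j);
    double sg = 0, sb = 0;
    for (int i = 0; i < n; ++i) {
      sg += dy[i] * xh[i];
      sb += dy[i];
    }
    dgamma[j] = sg;
    dbeta[j] = sb;
    const double g = gamma[j], is = istd[j];
    const double m1 = g * sb / n, m2 = g * sg / n;
    double *d = &dx(0, j);
    for (int i = 0; i < n; ++i) {
      d[i] = (dy[i] * g - m1 - xh[i] * m2) * is;
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Max pooling (width 2) over the time axis of [b, l, c]; returns pooled
// values and the take-odd mask for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool2(NumericVector x, int b, int l, int c) {
  const int lo = l / 2;
  NumericVector y((size_t)b * lo * c);
  LogicalVector takeodd((size_t)b * lo * c);
  const double *src = x.begin();
  double *dst = y.begin();
  int *mk = takeodd.begin();
  for (int ch = 0; ch < c; ++ch) {
    for (int t = 0; t < lo; ++t) {
      const double *a = src + ((size_t)ch * l + 2 * t) * b;
      const double *bb = a + b;
      double *yy = dst + ((size_t)ch * lo + t) * b;
      int *mm = mk + ((size_t)ch * lo + t) * b;
      for (int i = 0; i < b; ++i) {
        const bool odd = a[i] >= bb[i];
        mm[i] = odd;
        yy[i] = odd ? a[i] : bb[i];
      }
    }
  }
  y.attr("dim") = IntegerVector::create(b, lo, c);
  takeodd.attr("dim") = IntegerVector::create(b, lo, c);
  return List::create(_["y"] = y, _["take_odd"] = takeodd);
}

// Scatter the pooled gradient back to the unpooled layout.
// [[Rcpp::export]]
NumericVector cpp_maxpool2_backward(NumericVector dy, LogicalVector takeodd,
                                    int b, int l, int c) {
  const int lo = l / 2;
  NumericVector dx((size_t)b * l * c);
  const double *src = dy.begin();
  const int *mk = takeodd.begin();
  double *dst = dx.begin();
  for (int ch = 0; ch < c; ++ch) {
    for (int t = 0; t < lo; ++t) {
      const double *dd = src + ((size_t)ch * lo + t) * b;
      const int *mm = mk + ((size_t)ch * lo + t) * b;
      double *a = dst + ((size_t)ch * l + 2 * t) * b;
      double *bb = a + b;
      for (int i = 0; i < b; ++i) {
        if (mm[i]) a[i] = dd[i]; else bb[i] = dd[i];
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(b, l, c);
  return dx;
}
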