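// Low-level kernels for 2D convolution and pooling on single images
// stored as R arrays in (H, W, C) column-major layout.
//
// im2col unrolls k x k receptive fields into the rows of a matrix with
// output positions ordered column-major over (oh, ow) and patch entries
// ordered (ki, kj, c) with ki fastest, so a convolution is a single
// matrix product with a (k*k*C_in, C_out) weight matrix.

#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export]]
NumericMatrix im2col_hwc(NumericVector x, int H, int W, int C,
                         int k, int stride, int pad) {
  const int oh = out_size(H, k, stride, pad);
  const int ow = out_size(W, k, stride, pad);
  const int L = oh * ow;
  NumericMatrix cols(L, k * k * C);
  const double* px = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int col = ki + k * (kj + k * c);
        double* pc = &cols(0, col);
        for (int j = 0; j < ow; ++j) {
          const int w = j * stride - pad + kj;
          const bool w_ok = (w >= 0 && w < W);
          for (int i = 0; i < oh; ++i) {
            const int h = i * stride - pad + ki;
            double v = 0.0;
            if (w_ok && h >= 0 && h < H)
              v = px[h + H * (w + W * c)];
            pc[i + oh * j] = v;
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector col2im_hwc(NumericMatrix cols, int H, int W, int C,
                         int k, int stride, int pad) {
  const int oh = out_size(H, k, stride, pad);
  const int ow = out_size(W, k, stride, pad);
  NumericVector x(H * W * C);
  double* px = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int col = ki + k * (kj + k * c);
        const double* pc = &cols(0, col);
        for (int j = 0; j < ow; ++j) {
          const int w = j * stride - pad + kj;
          if (w < 0 || w >= W) continue;
          for (int i = 0; i < oh; ++i) {
            const int h = i * stride - pad + ki;
            if (h < 0 || h >= H) continue;
            px[h + H * (w + W * c)] += pc[i + oh * j];
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C);
  return x;
}

// [[Rcpp::export]]
List maxpool_fwd(NumericVector x, int H, int W, int C,
                 int k, int stride, int pad) {
  const int oh = out_size(H, k, stride, pad);
  const int ow = out_size(W, k, stride, pad);
  NumericVector y(oh * ow * C);
  IntegerVector arg(oh * ow * C);
  const double* px = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < ow; ++j) {
      for (int i = 0; i < oh; ++i) {
        double best = -DBL_MAX;
        int besti = -1;
        for (int kj = 0; kj < k; ++kj) {
          const int w = j * stride - pad + kj;
          if (w < 0 || w >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            const int h = i * stride - pad + ki;
            if (h < 0 || h >= H) continue;
            const int idx = h + H * (w + W * c);
            if (px[idx] > best) { best = px[idx]; besti = idx; }
          }
        }
        const int o = i + oh * (j + ow * c);
        y[o] = (besti >= 0) ? best : 0.0;
        arg[o] = besti;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(oh, ow, C);
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd(NumericVector dy, IntegerVector argmax,
                          int H, int W, int C) {
  NumericVector dx(H * W * C);
  for (int o = 0; o < dy.size(); ++o) {
    const int idx = argmax[o];
    if (idx >= 0) dx[idx] += dy[o];
  }
  dx.attr("dim") = IntegerVector::create(H, W, C);
  return dx;
}

// [[Rcpp::export]]
NumericVector avgpool_fwd(NumericVector x, int H, int W, int C,
                          int k, int stride) {
  const int oh = out_size(H, k, stride, 0);
  const int ow = out_size(W, k, stride, 0);
  NumericVector y(oh * ow * C);
  const double* px = x.begin();
  const double inv = 1.0 / (k * k);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < ow; ++j)
      for (int i = 0; i < oh; ++i) {
        double s = 0.0;
        for (int kj = 0; kj < k; ++kj)
          for (int ki = 0; ki < k; ++ki)
            s += px[(i * stride + ki) + H * ((j * stride + kj) + W * c)];
        y[i + oh * (j + ow * c)] = s * inv;
      }
  y.attr("dim") = IntegerVector::create(oh, ow, C);
  return y;
}

// [[Rcpp::export]]
NumericVector avgpool_bwd(NumericVector dy, int H, int W, int C,
                          int k, int stride) {
  const int oh = out_size(H, k, stride, 0);
  const int ow = out_size(W, k, stride, 0);
  NumericVector dx(H * W * C);
  const double inv = 1.0 / (k * k);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < ow; ++j)
      for (int i = 0; i < oh; ++i) {
        const double g = dy[i + oh * (j + ow * c)] * inv;
        for (int kj = 0; kj < k; ++kj)
          for (int ki = 0; ki < k; ++ki)
            dx[(i * stride + ki) + H * ((j * stride + kj) + W * c)] += g;
      }
  dx.attr("dim") = IntegerVector::create(H, W, C);
  return dx;
}
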