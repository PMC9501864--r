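// Low-level kernels for the convolutional network: im2col / col2im and
// 2x2 max pooling. Feature maps are R arrays with dim (H, W, C),
// column-major. im2col lays out patch rows as c-major, then kernel column,
// then kernel row (r = (c*k + kj)*k + ki), and patch columns as output
// position with the output row fastest, so a conv forward is a single
// matrix product W (outC x C*k*k) %*% cols.

#include <Rcpp.h>
using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int k, int stride, int pad) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2];
  const int oH = out_size(H, k, stride, pad);
  const int oW = out_size(W, k, stride, pad);
  NumericMatrix cols(C * k * k, oH * oW);
  const double* px = x.begin();
  double* pc = cols.begin();
  const int nrow = C * k * k;
  for (int ow = 0; ow < oW; ++ow) {
    for (int oh = 0; oh < oH; ++oh) {
      const int colidx = ow * oH + oh;
      double* dst = pc + (size_t)colidx * nrow;
      const int i0 = oh * stride - pad;
      const int j0 = ow * stride - pad;
      for (int c = 0; c < C; ++c) {
        const double* plane = px + (size_t)c * H * W;
        for (int kj = 0; kj < k; ++kj) {
          const int j = j0 + kj;
          for (int ki = 0; ki < k; ++ki) {
            const int i = i0 + ki;
            double v = 0.0;
            if (i >= 0 && i < H && j >= 0 && j < W)
              v = plane[(size_t)j * H + i];
            dst[((size_t)c * k + kj) * k + ki] = v;
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C,
                         int k, int stride, int pad) {
  const int oH = out_size(H, k, stride, pad);
  const int oW = out_size(W, k, stride, pad);
  NumericVector x(H * W * C);
  x.attr("dim") = IntegerVector::create(H, W, C);
  double* px = x.begin();
  const double* pc = cols.begin();
  const int nrow = C * k * k;
  for (int ow = 0; ow < oW; ++ow) {
    for (int oh = 0; oh < oH; ++oh) {
      const int colidx = ow * oH + oh;
      const double* src = pc + (size_t)colidx * nrow;
      const int i0 = oh * stride - pad;
      const int j0 = ow * stride - pad;
      for (int c = 0; c < C; ++c) {
        double* plane = px + (size_t)c * H * W;
        for (int kj = 0; kj < k; ++kj) {
          const int j = j0 + kj;
          if (j < 0 || j >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            const int i = i0 + ki;
            if (i < 0 || i >= H) continue;
            plane[(size_t)j * H + i] += src[((size_t)c * k + kj) * k + ki];
          }
        }
      }
    }
  }
  return x;
}

// 2x2 max pooling, stride 2. Returns the pooled map and the 1-based linear
// argmax index into the input array (for the backward pass).
// [[Rcpp::export]]
List maxpool2_fwd_cpp(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2];
  const int oH = H / 2, oW = W / 2;
  NumericVector y(oH * oW * C);
  IntegerVector arg(oH * oW * C);
  y.attr("dim") = IntegerVector::create(oH, oW, C);
  arg.attr("dim") = IntegerVector::create(oH, oW, C);
  const double* px = x.begin();
  for (int c = 0; c < C; ++c) {
    const size_t off = (size_t)c * H * W;
    for (int ow = 0; ow < oW; ++ow) {
      for (int oh = 0; oh < oH; ++oh) {
        double best = -1e300;
        size_t besti = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const size_t idx = off + (size_t)(ow * 2 + dj) * H + oh * 2 + di;
            if (px[idx] > best) { best = px[idx]; besti = idx; }
          }
        }
        const size_t oidx = (size_t)c * oH * oW + (size_t)ow * oH + oh;
        y[oidx] = best;
        arg[oidx] = (int)besti + 1;
      }
    }
  }
  return List::create(Named("y") = y, Named("argmax") = arg);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(NumericVector dy, IntegerVector argmax,
                               IntegerVector in_dim) {
  NumericVector dx((size_t)in_dim[0] * in_dim[1] * in_dim[2]);
  dx.attr("dim") = in_dim;
  for (R_xlen_t i = 0; i < dy.size(); ++i)
    dx[argmax[i] - 1] += dy[i];
  return dx;
}
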