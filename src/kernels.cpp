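#include <Rcpp.h>
using namespace Rcpp;

// Activation tensors are stored channel-first: dim(x) = c(C, H, W, N),
// column-major, so the channel index varies fastest.  Patch rows are ordered
// (c, kh, kw) with c fastest; patch columns are ordered (oh, ow, n) with oh
// fastest, matching the (C_out, oH, oW, N) layout of conv outputs.

static inline int out_dim(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int C, int H, int W, int N,
                         int k, int stride, int pad) {
  const int oH = out_dim(H, k, stride, pad);
  const int oW = out_dim(W, k, stride, pad);
  NumericMatrix cols(C * k * k, oH * oW * N);
  const double *xp = x.begin();
  double *cp = cols.begin();
  const int rows = C * k * k;
  for (int n = 0; n < N; ++n) {
    const double *xn = xp + (size_t)n * C * H * W;
    for (int ow = 0; ow < oW; ++ow) {
      for (int oh = 0; oh < oH; ++oh) {
        double *col = cp + (size_t)rows * (oh + (size_t)oH * (ow + (size_t)oW * n));
        for (int kj = 0; kj < k; ++kj) {
          int w = ow * stride - pad + kj;
          for (int ki = 0; ki < k; ++ki) {
            int h = oh * stride - pad + ki;
            double *dst = col + C * (ki + k * kj);
            if (h < 0 || h >= H || w < 0 || w >= W) {
              for (int c = 0; c < C; ++c) dst[c] = 0.0;
            } else {
              const double *src = xn + (size_t)C * (h + (size_t)H * w);
              for (int c = 0; c < C; ++c) dst[c] = src[c];
            }
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int C, int H, int W, int N,
                         int k, int stride, int pad) {
  const int oH = out_dim(H, k, stride, pad);
  const int oW = out_dim(W, k, stride, pad);
  NumericVector x((size_t)C * H * W * N);
  double *xp = x.begin();
  const double *cp = cols.begin();
  const int rows = C * k * k;
  for (int n = 0; n < N; ++n) {
    double *xn = xp + (size_t)n * C * H * W;
    for (int ow = 0; ow < oW; ++ow) {
      for (int oh = 0; oh < oH; ++oh) {
        const double *col = cp + (size_t)rows * (oh + (size_t)oH * (ow + (size_t)oW * n));
        for (int kj = 0; kj < k; ++kj) {
          int w = ow * stride - pad + kj;
          if (w < 0 || w >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            int h = oh * stride - pad + ki;
            if (h < 0 || h >= H) continue;
            const double *src = col + C * (ki + k * kj);
            double *dst = xn + (size_t)C * (h + (size_t)H * w);
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
  return x;
}

// Max pooling over k x k windows per channel; padded cells are ignored.
// Returns the pooled tensor and 1-based argmax indices into x.
// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, int C, int H, int W, int N,
                     int k, int stride, int pad) {
  const int oH = out_dim(H, k, stride, pad);
  const int oW = out_dim(W, k, stride, pad);
  NumericVector out((size_t)C * oH * oW * N);
  IntegerVector arg((size_t)C * oH * oW * N);
  const double *xp = x.begin();
  double *op = out.begin();
  int *ap = arg.begin();
  for (int n = 0; n < N; ++n) {
    const size_t xoff = (size_t)n * C * H * W;
    for (int ow = 0; ow < oW; ++ow) {
      for (int oh = 0; oh < oH; ++oh) {
        size_t obase = (size_t)C * (oh + (size_t)oH * (ow + (size_t)oW * n));
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf;
          size_t besti = 0;
          for (int kj = 0; kj < k; ++kj) {
            int w = ow * stride - pad + kj;
            if (w < 0 || w >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int h = oh * stride - pad + ki;
              if (h < 0 || h >= H) continue;
              size_t xi = xoff + c + (size_t)C * (h + (size_t)H * w);
              if (xp[xi] > best) { best = xp[xi]; besti = xi; }
            }
          }
          op[obase + c] = best;
          ap[obase + c] = (int)(besti + 1);
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector dy, IntegerVector argmax, int n_in) {
  NumericVector dx(n_in);
  double *dp = dx.begin();
  const double *gp = dy.begin();
  const int *ap = argmax.begin();
  const R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; ++i) dp[ap[i] - 1] += gp[i];
  return dx;
}
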