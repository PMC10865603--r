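// Low-level 1-D network primitives.
//
// Layout conventions (shared with the R side):
//   signals   : arma::mat, channels x time
//   conv bank : arma::cube, (out_channels, in_channels, kernel)
//
// Convolutions are expressed as a sum over kernel taps of shifted
// matrix products, so the heavy lifting is BLAS gemm rather than
// scalar loops.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat pad_cols(const mat& x, int pad_left, int pad_right) {
  if (pad_left == 0 && pad_right == 0) return x;
  mat xp(x.n_rows, x.n_cols + pad_left + pad_right, fill::zeros);
  xp.cols(pad_left, pad_left + x.n_cols - 1) = x;
  return xp;
}

static uvec tap_index(int k, int dilation, int stride, int n_out) {
  uvec idx(n_out);
  for (int t = 0; t < n_out; ++t) idx[t] = (uword)(k * dilation + t * stride);
  return idx;
}

// [[Rcpp::export]]
arma::mat cpp_conv1d_forward(const arma::mat& x, const arma::cube& w,
                             const arma::vec& b, int stride, int dilation,
                             int pad_left, int pad_right) {
  const int K = w.n_slices;
  mat xp = pad_cols(x, pad_left, pad_right);
  const int span = (K - 1) * dilation + 1;
  const int n_out = (int)((xp.n_cols - span) / stride) + 1;
  mat out(w.n_rows, n_out);
  out.each_col() = b;
  for (int k = 0; k < K; ++k) {
    if (stride == 1) {
      out += w.slice(k) * xp.cols(k * dilation, k * dilation + n_out - 1);
    } else {
      out += w.slice(k) * xp.cols(tap_index(k, dilation, stride, n_out));
    }
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv1d_backward(const arma::mat& x, const arma::cube& w,
                               const arma::mat& grad_out, int stride,
                               int dilation, int pad_left, int pad_right) {
  const int K = w.n_slices;
  mat xp = pad_cols(x, pad_left, pad_right);
  const int n_out = grad_out.n_cols;
  cube grad_w(size(w), fill::zeros);
  mat grad_xp(xp.n_rows, xp.n_cols, fill::zeros);
  for (int k = 0; k < K; ++k) {
    if (stride == 1) {
      const int a = k * dilation, bcol = k * dilation + n_out - 1;
      grad_w.slice(k) = grad_out * xp.cols(a, bcol).t();
      grad_xp.cols(a, bcol) += w.slice(k).t() * grad_out;
    } else {
      uvec idx = tap_index(k, dilation, stride, n_out);
      grad_w.slice(k) = grad_out * xp.cols(idx).t();
      mat add = w.slice(k).t() * grad_out;
      for (int t = 0; t < n_out; ++t) grad_xp.col(idx[t]) += add.col(t);
    }
  }
  mat grad_x = grad_xp.cols(pad_left, pad_left + x.n_cols - 1);
  vec grad_b = sum(grad_out, 1);
  return Rcpp::List::create(Rcpp::Named("grad_x") = grad_x,
                            Rcpp::Named("grad_w") = grad_w,
                            Rcpp::Named("grad_b") = grad_b);
}

// Max pooling, stride 1, explicit padding (pad entries never win: -inf).
// [[Rcpp::export]]
Rcpp::List cpp_maxpool1d_forward(const arma::mat& x, int k, int pad_left,
                                 int pad_right) {
  const int C = x.n_rows, L = x.n_cols;
  const int n_out = L + pad_left + pad_right - k + 1;
  mat out(C, n_out);
  umat amax(C, n_out);
  for (int c = 0; c < C; ++c) {
    for (int t = 0; t < n_out; ++t) {
      double best = -datum::inf;
      int bi = -1;
      for (int j = 0; j < k; ++j) {
        int src = t + j - pad_left;
        if (src < 0 || src >= L) continue;
        if (x(c, src) > best) { best = x(c, src); bi = src; }
      }
      out(c, t) = best;
      amax(c, t) = (uword)bi;
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("argmax") = amax);
}

// [[Rcpp::export]]
arma::mat cpp_maxpool1d_backward(const arma::mat& grad_out,
                                 const arma::umat& argmax, int L) {
  mat grad_x(grad_out.n_rows, L, fill::zeros);
  for (uword c = 0; c < grad_out.n_rows; ++c)
    for (uword t = 0; t < grad_out.n_cols; ++t)
      grad_x(c, argmax(c, t)) += grad_out(c, t);
  return grad_x;
}

// Rational resampling core: upsample by p (zero stuffing), FIR filter h,
// downsample by q. Output m taps y[m] = sum_j h[j] * xu[m*q + delay - j]
// where xu is the zero-stuffed input and delay = (len(h)-1)/2 centres the
// (odd, symmetric) filter so the output is delay-free.
// [[Rcpp::export]]
arma::vec cpp_upfirdn(const arma::vec& x, const arma::vec& h, int p, int q,
                      int n_out) {
  const int L = x.n_elem, nh = h.n_elem;
  const int delay = (nh - 1) / 2;
  vec y(n_out, fill::zeros);
  for (int m = 0; m < n_out; ++m) {
    const long long centre = (long long)m * q + delay;
    // xu[i] nonzero only when i % p == 0, value x[i / p]
    // j ranges over taps with 0 <= centre - j < L*p
    long long jlo = centre - ((long long)L * p - 1);
    if (jlo < 0) jlo = 0;
    long long jhi = centre < (nh - 1) ? centre : (nh - 1);
    // first j >= jlo with (centre - j) % p == 0
    long long r = (centre - jlo) % p;
    double acc = 0.0;
    for (long long j = jlo + r; j <= jhi; j += p) {
      acc += h[j] * x[(centre - j) / p];
    }
    y[m] = acc;
  }
  return y;
}

// Adaptive average pooling to n_out bins; bin i covers
// [floor(i*L/n_out), ceil((i+1)*L/n_out)) as in the usual framework
// convention, so bins tile the input with at most one-sample overlap.
// [[Rcpp::export]]
arma::mat cpp_adaptive_avgpool_forward(const arma::mat& x, int n_out) {
  const int L = x.n_cols;
  mat out(x.n_rows, n_out);
  for (int i = 0; i < n_out; ++i) {
    int a = (int)std::floor((double)i * L / n_out);
    int b = (int)std::ceil((double)(i + 1) * L / n_out);
    out.col(i) = mean(x.cols(a, b - 1), 1);
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_adaptive_avgpool_backward(const arma::mat& grad_out, int L) {
  const int n_out = grad_out.n_cols;
  mat grad_x(grad_out.n_rows, L, fill::zeros);
  for (int i = 0; i < n_out; ++i) {
    int a = (int)std::floor((double)i * L / n_out);
    int b = (int)std::ceil((double)(i + 1) * L / n_out);
    grad_x.cols(a, b - 1).each_col() += grad_out.col(i) / (b - a);
  }
  return grad_x;
}
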