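// Integer-only inference kernels. Activations are INT8 values carried in R
// integer vectors/matrices; accumulators are 64-bit. In fixed-point mode no
// floating-point value influences any integer tensor: requantization uses the
// precomputed 31-bit mantissa + right-shift pairs stored in the quantized
// model. The float-multiplier path is retained for debugging/parity checks.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline int clamp_i8(int64_t v) {
  if (v < -128) return -128;
  if (v > 127) return 127;
  return (int)v;
}

// round(v * m * 2^-shift) with rounding half away from zero, 64-bit exact.
static inline int64_t fixed_rescale(int64_t acc, int32_t m, int shift) {
  int64_t v = acc * (int64_t)m;
  if (shift <= 0) return v << (-shift);
  const int64_t half = (int64_t)1 << (shift - 1);
  if (v >= 0) return (v + half) >> shift;
  return -((-v + half) >> shift);
}

static inline int64_t float_rescale(int64_t acc, double M) {
  return (int64_t)std::llround((double)acc * M);
}

// [[Rcpp::export(name = ".quantize_multiplier")]]
List quantize_multiplier(double M) {
  if (M <= 0) stop("multiplier must be positive");
  int e;
  double f = std::frexp(M, &e);         // M = f * 2^e, f in [0.5, 1)
  int64_t m = (int64_t)std::llround(f * 2147483648.0);  // f * 2^31
  if (m == 2147483648LL) { m /= 2; ++e; }
  return List::create(_["mantissa"] = (int)m, _["shift"] = 31 - e);
}

// [[Rcpp::export(name = ".requantize_int")]]
IntegerVector requantize_int(NumericVector acc, IntegerVector mantissa,
                             IntegerVector shift, NumericVector M,
                             int zero_point, bool fixed_point) {
  const R_xlen_t n = acc.size();
  const bool perch = mantissa.size() == n;
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const int64_t a = (int64_t)acc[i];
    const R_xlen_t j = perch ? i : 0;
    int64_t r = fixed_point ? fixed_rescale(a, mantissa[j], shift[j])
                            : float_rescale(a, M[j]);
    out[i] = clamp_i8(r + zero_point);
  }
  return out;
}

// Integer conv1d. x: L x Cin int matrix (INT8 values), Wq: (k*Cin) x Cout
// (rows tap-major then channel, matching the float executor's im2col order).
// [[Rcpp::export(name = ".conv1d_int8")]]
IntegerMatrix conv1d_int8(IntegerMatrix x, IntegerMatrix Wq,
                          IntegerVector bias, int zp_in,
                          IntegerVector mantissa, IntegerVector shift,
                          NumericVector M, int zp_out,
                          int k, int stride, int dilation,
                          int padL, int padR, bool fixed_point) {
  const int L = x.nrow(), Cin = x.ncol(), Cout = Wq.ncol();
  const int effk = (k - 1) * dilation + 1;
  const int Lout = (L + padL + padR - effk) / stride + 1;
  const int R = k * Cin;
  const int* xp = INTEGER(x);
  const int* wp = INTEGER(Wq);
  IntegerMatrix y(Lout, Cout);
  int* yp = INTEGER(y);
  // zero-padding contributes nothing: real 0 maps to zp_in, (q - zp_in) = 0
  for (int t = 0; t < Lout; ++t) {
    const int base = t * stride - padL;
    for (int o = 0; o < Cout; ++o) {
      const int* wo = wp + (size_t)o * R;
      int64_t acc = bias[o];
      for (int tap = 0; tap < k; ++tap) {
        const int p = base + tap * dilation;
        if (p < 0 || p >= L) continue;
        const int* wt = wo + tap * Cin;
        for (int c = 0; c < Cin; ++c)
          acc += (int64_t)(xp[p + (size_t)c * L] - zp_in) * wt[c];
      }
      int64_t r = fixed_point ? fixed_rescale(acc, mantissa[o], shift[o])
                              : float_rescale(acc, M[o]);
      yp[t + (size_t)o * Lout] = clamp_i8(r + zp_out);
    }
  }
  return y;
}

// Integer depthwise conv1d. Wq: k x C.
// [[Rcpp::export(name = ".dwconv1d_int8")]]
IntegerMatrix dwconv1d_int8(IntegerMatrix x, IntegerMatrix Wq,
                            IntegerVector bias, int zp_in,
                            IntegerVector mantissa, IntegerVector shift,
                            NumericVector M, int zp_out,
                            int stride, int dilation, int padL, int padR,
                            bool fixed_point) {
  const int L = x.nrow(), C = x.ncol(), k = Wq.nrow();
  const int effk = (k - 1) * dilation + 1;
  const int Lout = (L + padL + padR - effk) / stride + 1;
  IntegerMatrix y(Lout, C);
  for (int t = 0; t < Lout; ++t) {
    const int base = t * stride - padL;
    for (int c = 0; c < C; ++c) {
      int64_t acc = bias[c];
      for (int tap = 0; tap < k; ++tap) {
        const int p = base + tap * dilation;
        if (p < 0 || p >= L) continue;
        acc += (int64_t)(x(p, c) - zp_in) * Wq(tap, c);
      }
      int64_t r = fixed_point ? fixed_rescale(acc, mantissa[c], shift[c])
                              : float_rescale(acc, M[c]);
      y(t, c) = clamp_i8(r + zp_out);
    }
  }
  return y;
}

// Integer dense: x length n_in, Wq n_in x n_out (per-output-channel quant).
// [[Rcpp::export(name = ".dense_int8")]]
IntegerVector dense_int8(IntegerVector x, IntegerMatrix Wq, IntegerVector bias,
                         int zp_in, IntegerVector mantissa, IntegerVector shift,
                         NumericVector M, int zp_out, bool fixed_point) {
  const int n_in = x.size(), n_out = Wq.ncol();
  const int* xp = INTEGER(x);
  const int* wp = INTEGER(Wq);
  IntegerVector y(n_out);
  for (int o = 0; o < n_out; ++o) {
    const int* wo = wp + (size_t)o * n_in;
    int64_t acc = bias[o];
    for (int i = 0; i < n_in; ++i)
      acc += (int64_t)(xp[i] - zp_in) * wo[i];
    int64_t r = fixed_point ? fixed_rescale(acc, mantissa[o], shift[o])
                            : float_rescale(acc, M[o]);
    y[o] = clamp_i8(r + zp_out);
  }
  return y;
}

// Residual add: each addend rescaled to the output edge, then saturating add.
// [[Rcpp::export(name = ".add_int8")]]
IntegerMatrix add_int8(IntegerMatrix a, IntegerMatrix b,
                       int zp_a, int zp_b,
                       int mant_a, int shift_a, double M_a,
                       int mant_b, int shift_b, double M_b,
                       int zp_out, bool fixed_point) {
  const int L = a.nrow(), C = a.ncol();
  IntegerMatrix y(L, C);
  for (int c = 0; c < C; ++c)
    for (int t = 0; t < L; ++t) {
      const int64_t qa = a(t, c) - zp_a, qb = b(t, c) - zp_b;
      int64_t ra = fixed_point ? fixed_rescale(qa, mant_a, shift_a)
                               : float_rescale(qa, M_a);
      int64_t rb = fixed_point ? fixed_rescale(qb, mant_b, shift_b)
                               : float_rescale(qb, M_b);
      y(t, c) = clamp_i8(ra + rb + zp_out);
    }
  return y;
}

// Global average pooling in the integer domain: INT32 column sums rescaled by
// s_in / (L * s_out) (the 1/L folded into the multiplier).
// [[Rcpp::export(name = ".gap_int8")]]
IntegerVector gap_int8(IntegerMatrix x, int zp_in, int mantissa, int shift,
                       double M, int zp_out, bool fixed_point) {
  const int L = x.nrow(), C = x.ncol();
  IntegerVector y(C);
  for (int c = 0; c < C; ++c) {
    int64_t acc = 0;
    for (int t = 0; t < L; ++t) acc += x(t, c) - zp_in;
    int64_t r = fixed_point ? fixed_rescale(acc, mantissa, shift)
                            : float_rescale(acc, M);
    y[c] = clamp_i8(r + zp_out);
  }
  return y;
}
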