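// Batched float kernels for the 1D convolutional layer kinds.
// Activations are cubes (length x channels x batch); conv weights are cubes
// (kernel x c_in x c_out). Convolutions go through im2col + GEMM so the heavy
// lifting lands in BLAS; depthwise convolutions are direct loops (tiny tap
// counts make GEMM pointless there).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int conv_out_len(int L, int k, int stride, int dilation,
                               int padL, int padR) {
  const int effk = (k - 1) * dilation + 1;
  return (L + padL + padR - effk) / stride + 1;
}

// im2col for one batch slice into a contiguous column-major buffer of
// (k*c_in) rows x L_out columns; rows ordered tap-major then channel
// (row = tap * c_in + c). Out-of-range taps contribute zero.
static void im2col(const arma::mat& x, int k, int stride, int dilation,
                   int padL, int Lout, double* out) {
  const int Cin = x.n_cols;
  const int L = x.n_rows;
  const int R = k * Cin;
  std::fill(out, out + (size_t)R * Lout, 0.0);
  const double* xp = x.memptr();
  for (int t = 0; t < Lout; ++t) {
    const int base = t * stride - padL;
    double* col = out + (size_t)t * R;
    for (int tap = 0; tap < k; ++tap) {
      const int p = base + tap * dilation;
      if (p < 0 || p >= L) continue;
      double* dst = col + tap * Cin;
      for (int c = 0; c < Cin; ++c)
        dst[c] = xp[p + (size_t)c * L];
    }
  }
}

// [[Rcpp::export(name = ".conv1d_fwd")]]
arma::cube conv1d_fwd(const arma::cube& x, const arma::cube& W,
                      const arma::vec& b, int stride, int dilation,
                      int padL, int padR) {
  const int L = x.n_rows, Cin = x.n_cols, B = x.n_slices;
  const int k = W.n_rows, Cout = W.n_slices;
  const int Lout = conv_out_len(L, k, stride, dilation, padL, padR);
  // weight matrix (Cout x k*Cin), rows follow im2col row order
  arma::mat Wm(Cout, k * Cin);
  for (int o = 0; o < Cout; ++o)
    for (int tap = 0; tap < k; ++tap)
      for (int c = 0; c < Cin; ++c)
        Wm(o, tap * Cin + c) = W(tap, c, o);
  arma::cube y(Lout, Cout, B);
  // chunked batch GEMM: one multiply per chunk of windows keeps the GEMM
  // wide enough for BLAS efficiency without large buffers
  const int chunk = std::max(1, std::min(B, 32));
  arma::mat cols(k * Cin, (size_t)Lout * chunk);
  for (int s0 = 0; s0 < B; s0 += chunk) {
    const int nb = std::min(chunk, B - s0);
    if (nb != chunk) cols.set_size(k * Cin, (size_t)Lout * nb);
    for (int s = 0; s < nb; ++s)
      im2col(x.slice(s0 + s), k, stride, dilation, padL, Lout,
             cols.colptr((size_t)s * Lout));
    arma::mat out = Wm * cols;            // Cout x (Lout*nb)
    out.each_col() += b;
    for (int s = 0; s < nb; ++s)
      y.slice(s0 + s) =
        out.cols((size_t)s * Lout, (size_t)(s + 1) * Lout - 1).t();
  }
  return y;
}

// [[Rcpp::export(name = ".conv1d_bwd")]]
List conv1d_bwd(const arma::cube& x, const arma::cube& W, const arma::cube& dy,
                int stride, int dilation, int padL, int padR) {
  const int L = x.n_rows, Cin = x.n_cols, B = x.n_slices;
  const int k = W.n_rows, Cout = W.n_slices;
  const int Lout = dy.n_rows;
  arma::mat Wm(Cout, k * Cin);
  for (int o = 0; o < Cout; ++o)
    for (int tap = 0; tap < k; ++tap)
      for (int c = 0; c < Cin; ++c)
        Wm(o, tap * Cin + c) = W(tap, c, o);
  arma::mat dWm(Cout, k * Cin, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::cube dx(L, Cin, B, arma::fill::zeros);
  const int chunk = std::max(1, std::min(B, 32));
  arma::mat cols(k * Cin, (size_t)Lout * chunk);
  arma::mat g(Cout, (size_t)Lout * chunk);
  for (int s0 = 0; s0 < B; s0 += chunk) {
    const int nb = std::min(chunk, B - s0);
    if (nb != chunk) {
      cols.set_size(k * Cin, (size_t)Lout * nb);
      g.set_size(Cout, (size_t)Lout * nb);
    }
    for (int s = 0; s < nb; ++s) {
      im2col(x.slice(s0 + s), k, stride, dilation, padL, Lout,
             cols.colptr((size_t)s * Lout));
      g.cols((size_t)s * Lout, (size_t)(s + 1) * Lout - 1) =
        dy.slice(s0 + s).t();
    }
    dWm += g * cols.t();
    db += arma::sum(g, 1);
    arma::mat dcols = Wm.t() * g;         // k*Cin x (Lout*nb)
    for (int s = 0; s < nb; ++s) {
      arma::mat& dxs = dx.slice(s0 + s);
      double* dxp = dxs.memptr();
      const double* dc = dcols.colptr((size_t)s * Lout);
      for (int t = 0; t < Lout; ++t) {
        const int base = t * stride - padL;
        const double* col = dc + (size_t)t * (k * Cin);
        for (int tap = 0; tap < k; ++tap) {
          const int p = base + tap * dilation;
          if (p < 0 || p >= L) continue;
          const double* src = col + tap * Cin;
          for (int c = 0; c < Cin; ++c)
            dxp[p + (size_t)c * L] += src[c];
        }
      }
    }
  }
  arma::cube dW(k, Cin, Cout);
  for (int o = 0; o < Cout; ++o)
    for (int tap = 0; tap < k; ++tap)
      for (int c = 0; c < Cin; ++c)
        dW(tap, c, o) = dWm(o, tap * Cin + c);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export(name = ".dwconv1d_fwd")]]
arma::cube dwconv1d_fwd(const arma::cube& x, const arma::mat& W,
                        const arma::vec& b, int stride, int dilation,
                        int padL, int padR) {
  const int L = x.n_rows, C = x.n_cols, B = x.n_slices;
  const int k = W.n_rows;
  const int Lout = conv_out_len(L, k, stride, dilation, padL, padR);
  arma::cube y(Lout, C, B);
  for (int s = 0; s < B; ++s) {
    const arma::mat& xs = x.slice(s);
    arma::mat& ys = y.slice(s);
    for (int t = 0; t < Lout; ++t) {
      const int base = t * stride - padL;
      for (int c = 0; c < C; ++c) {
        double acc = b(c);
        for (int tap = 0; tap < k; ++tap) {
          const int p = base + tap * dilation;
          if (p < 0 || p >= L) continue;
          acc += xs(p, c) * W(tap, c);
        }
        ys(t, c) = acc;
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".dwconv1d_bwd")]]
List dwconv1d_bwd(const arma::cube& x, const arma::mat& W, const arma::cube& dy,
                  int stride, int dilation, int padL, int padR) {
  const int L = x.n_rows, C = x.n_cols, B = x.n_slices;
  const int k = W.n_rows;
  const int Lout = dy.n_rows;
  arma::mat dW(k, C, arma::fill::zeros);
  arma::vec db(C, arma::fill::zeros);
  arma::cube dx(L, C, B, arma::fill::zeros);
  for (int s = 0; s < B; ++s) {
    const arma::mat& xs = x.slice(s);
    const arma::mat& gs = dy.slice(s);
    arma::mat& dxs = dx.slice(s);
    for (int t = 0; t < Lout; ++t) {
      const int base = t * stride - padL;
      for (int c = 0; c < C; ++c) {
        const double g = gs(t, c);
        db(c) += g;
        for (int tap = 0; tap < k; ++tap) {
          const int p = base + tap * dilation;
          if (p < 0 || p >= L) continue;
          dW(tap, c) += g * xs(p, c);
          dxs(p, c) += g * W(tap, c);
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// Non-overlapping max pooling (pool == stride), valid mode.
// [[Rcpp::export(name = ".maxpool1d_fwd")]]
List maxpool1d_fwd(const arma::cube& x, int pool) {
  const int L = x.n_rows, C = x.n_cols, B = x.n_slices;
  const int Lout = L / pool;
  arma::cube y(Lout, C, B);
  arma::ucube idx(Lout, C, B);   // winning input row per output
  for (int s = 0; s < B; ++s) {
    const double* xp = x.slice_memptr(s);
    double* yp = y.slice_memptr(s);
    arma::uword* ip = idx.slice_memptr(s);
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + (size_t)c * L;
      double* yc = yp + (size_t)c * Lout;
      arma::uword* ic = ip + (size_t)c * Lout;
      for (int t = 0; t < Lout; ++t) {
        int best = t * pool;
        double bv = xc[best];
        for (int p = 1; p < pool; ++p) {
          const int r = t * pool + p;
          if (xc[r] > bv) { bv = xc[r]; best = r; }
        }
        yc[t] = bv;
        ic[t] = best;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool1d_bwd")]]
arma::cube maxpool1d_bwd(const arma::cube& dy, const arma::ucube& idx,
                         int Lin) {
  const int Lout = dy.n_rows, C = dy.n_cols, B = dy.n_slices;
  arma::cube dx(Lin, C, B, arma::fill::zeros);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c)
      for (int t = 0; t < Lout; ++t)
        dx(idx(t, c, s), c, s) += dy(t, c, s);
  return dx;
}
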