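// Low-level convolution kernels for the segmentation network.
//
// All tensors use R's column-major layout:
//   activations: (H, W, C, N); conv weights: (kh, kw, Cin, Cout);
//   transposed-conv weights: (kh, kw, Cout, Cin) -- the layout of the
//   underlying stride-2 convolution whose adjoint the transposed conv is.
//
// Convolutions are realised as im2col + GEMM. A precomputed integer map
// (kernel tap x output pixel -> linear input index, or -1 for zero padding)
// serves both the gather (im2col) and the scatter-add (col2im) direction,
// which keeps zero and reflective padding on one code path.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

// pad_mode: 0 = zero, 1 = reflect (mirror without repeating the edge pixel)
inline int reflect_idx(int p, int n) {
  if (p < 0) p = -p;
  if (p >= n) p = 2 * n - 2 - p;
  return p;
}

arma::imat build_map(int H, int W, int kh, int kw, int stride, int dil,
                     int pad, int pad_mode, int Hout, int Wout) {
  arma::imat map(kh * kw, (arma::uword)Hout * Wout);
  for (int jo = 0; jo < Wout; ++jo) {
    for (int io = 0; io < Hout; ++io) {
      const arma::uword l = (arma::uword)io + (arma::uword)Hout * jo;
      for (int b = 0; b < kw; ++b) {
        int jj = jo * stride - pad + b * dil;
        for (int a = 0; a < kh; ++a) {
          int ii = io * stride - pad + a * dil;
          int iiw = ii, jjw = jj;
          bool inside = true;
          if (pad_mode == 1) {
            iiw = reflect_idx(ii, H);
            jjw = reflect_idx(jj, W);
          } else if (ii < 0 || ii >= H || jj < 0 || jj >= W) {
            inside = false;
          }
          map(a + kh * b, l) =
              inside ? (long long)(iiw + H * jjw) : (long long)-1;
        }
      }
    }
  }
  return map;
}

// Gather one image's channels into the im2col matrix (kh*kw*C x L).
void gather(const double* img, int HW, int C, const arma::imat& map,
            arma::mat& cols) {
  const int kk = map.n_rows;
  const arma::uword L = map.n_cols;
  for (arma::uword l = 0; l < L; ++l) {
    double* col = cols.colptr(l);
    for (int c = 0; c < C; ++c) {
      const double* ch = img + (arma::uword)HW * c;
      double* dst = col + (arma::uword)kk * c;
      for (int t = 0; t < kk; ++t) {
        const long long idx = map(t, l);
        dst[t] = (idx >= 0) ? ch[idx] : 0.0;
      }
    }
  }
}

// Scatter-add the columns back onto an image (adjoint of gather).
void scatter(double* img, int HW, int C, const arma::imat& map,
             const arma::mat& cols) {
  const int kk = map.n_rows;
  const arma::uword L = map.n_cols;
  for (arma::uword l = 0; l < L; ++l) {
    const double* col = cols.colptr(l);
    for (int c = 0; c < C; ++c) {
      double* ch = img + (arma::uword)HW * c;
      const double* src = col + (arma::uword)kk * c;
      for (int t = 0; t < kk; ++t) {
        const long long idx = map(t, l);
        if (idx >= 0) ch[idx] += src[t];
      }
    }
  }
}

inline IntegerVector dims_of(const NumericVector& x) {
  return x.attr("dim");
}

} // namespace

// [[Rcpp::export(name = ".cpp_conv2d_fw")]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                            int stride, int dil, int pad_mode) {
  IntegerVector dx = dims_of(x), dw = dims_of(w);
  const int H = dx[0], W = dx[1], Ci = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Co = dw[3];
  const int pad = dil * (kh - 1) / 2;
  const int Hout = (stride == 1) ? H : (H + 2 * pad - dil * (kh - 1) - 1) / stride + 1;
  const int Wout = (stride == 1) ? W : (W + 2 * pad - dil * (kw - 1) - 1) / stride + 1;
  const arma::uword L = (arma::uword)Hout * Wout;

  arma::imat map = build_map(H, W, kh, kw, stride, dil, pad, pad_mode, Hout, Wout);
  arma::mat Wm(w.begin(), (arma::uword)kh * kw * Ci, Co, false, true);
  NumericVector out((R_xlen_t)L * Co * N);
  out.attr("dim") = IntegerVector::create(Hout, Wout, Co, N);

  arma::mat cols((arma::uword)kh * kw * Ci, L);
  for (int n = 0; n < N; ++n) {
    gather(x.begin() + (R_xlen_t)H * W * Ci * n, H * W, Ci, map, cols);
    arma::mat ov(out.begin() + (R_xlen_t)L * Co * n, L, Co, false, true);
    ov = cols.t() * Wm;
    for (int co = 0; co < Co; ++co) ov.col(co) += b[co];
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_conv2d_bw")]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector dy,
                   int stride, int dil, int pad_mode) {
  IntegerVector dx_ = dims_of(x), dw_ = dims_of(w), dd = dims_of(dy);
  const int H = dx_[0], W = dx_[1], Ci = dx_[2], N = dx_[3];
  const int kh = dw_[0], kw = dw_[1], Co = dw_[3];
  const int Hout = dd[0], Wout = dd[1];
  const int pad = dil * (kh - 1) / 2;
  const arma::uword L = (arma::uword)Hout * Wout;

  arma::imat map = build_map(H, W, kh, kw, stride, dil, pad, pad_mode, Hout, Wout);
  arma::mat Wm(w.begin(), (arma::uword)kh * kw * Ci, Co, false, true);

  NumericVector dxo((R_xlen_t)H * W * Ci * N);
  dxo.attr("dim") = IntegerVector::create(H, W, Ci, N);
  NumericVector dwo((R_xlen_t)kh * kw * Ci * Co);
  dwo.attr("dim") = IntegerVector::create(kh, kw, Ci, Co);
  NumericVector dbo(Co);
  arma::mat dWm(dwo.begin(), (arma::uword)kh * kw * Ci, Co, false, true);
  arma::vec dbv(dbo.begin(), Co, false, true);

  arma::mat cols((arma::uword)kh * kw * Ci, L);
  for (int n = 0; n < N; ++n) {
    arma::mat dyv(dy.begin() + (R_xlen_t)L * Co * n, L, Co, false, true);
    gather(x.begin() + (R_xlen_t)H * W * Ci * n, H * W, Ci, map, cols);
    dWm += cols * dyv;
    dbv += arma::sum(dyv, 0).t();
    arma::mat dcols = Wm * dyv.t();
    scatter(dxo.begin() + (R_xlen_t)H * W * Ci * n, H * W, Ci, map, dcols);
  }
  return List::create(_["dx"] = dxo, _["dw"] = dwo, _["db"] = dbo);
}

// Transposed convolution, kernel 4, stride 2, pad 1: (H,W,Cin) -> (2H,2W,Cout).
// Forward is the scatter adjoint of the matching stride-2 convolution.
// [[Rcpp::export(name = ".cpp_tconv2d_fw")]]
NumericVector cpp_tconv2d_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector dx = dims_of(x), dw = dims_of(w);
  const int H = dx[0], W = dx[1], Ci = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Co = dw[2];
  const int H2 = 2 * H, W2 = 2 * W;
  const arma::uword L = (arma::uword)H * W;

  arma::imat map = build_map(H2, W2, kh, kw, 2, 1, 1, 0, H, W);
  arma::mat Wm(w.begin(), (arma::uword)kh * kw * Co, Ci, false, true);
  NumericVector out((R_xlen_t)H2 * W2 * Co * N);
  out.attr("dim") = IntegerVector::create(H2, W2, Co, N);

  for (int n = 0; n < N; ++n) {
    arma::mat Xv(x.begin() + (R_xlen_t)L * Ci * n, L, Ci, false, true);
    arma::mat dcols = Wm * Xv.t();
    double* optr = out.begin() + (R_xlen_t)H2 * W2 * Co * n;
    scatter(optr, H2 * W2, Co, map, dcols);
    for (int co = 0; co < Co; ++co) {
      double* ch = optr + (R_xlen_t)H2 * W2 * co;
      for (int p = 0; p < H2 * W2; ++p) ch[p] += b[co];
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_tconv2d_bw")]]
List cpp_tconv2d_bw(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector dx_ = dims_of(x), dw_ = dims_of(w);
  const int H = dx_[0], W = dx_[1], Ci = dx_[2], N = dx_[3];
  const int kh = dw_[0], kw = dw_[1], Co = dw_[2];
  const int H2 = 2 * H, W2 = 2 * W;
  const arma::uword L = (arma::uword)H * W;

  arma::imat map = build_map(H2, W2, kh, kw, 2, 1, 1, 0, H, W);
  arma::mat Wm(w.begin(), (arma::uword)kh * kw * Co, Ci, false, true);

  NumericVector dxo((R_xlen_t)L * Ci * N);
  dxo.attr("dim") = IntegerVector::create(H, W, Ci, N);
  NumericVector dwo((R_xlen_t)kh * kw * Co * Ci);
  dwo.attr("dim") = IntegerVector::create(kh, kw, Co, Ci);
  NumericVector dbo(Co);
  arma::mat dWm(dwo.begin(), (arma::uword)kh * kw * Co, Ci, false, true);

  arma::mat cols((arma::uword)kh * kw * Co, L);
  for (int n = 0; n < N; ++n) {
    const double* dptr = dy.begin() + (R_xlen_t)H2 * W2 * Co * n;
    gather(dptr, H2 * W2, Co, map, cols);
    arma::mat Xv(x.begin() + (R_xlen_t)L * Ci * n, L, Ci, false, true);
    arma::mat dXv(dxo.begin() + (R_xlen_t)L * Ci * n, L, Ci, false, true);
    dXv = cols.t() * Wm;
    dWm += cols * Xv;
    for (int co = 0; co < Co; ++co) {
      const double* ch = dptr + (R_xlen_t)H2 * W2 * co;
      double s = 0.0;
      for (int p = 0; p < H2 * W2; ++p) s += ch[p];
      dbo[co] += s;
    }
  }
  return List::create(_["dx"] = dxo, _["dw"] = dwo, _["db"] = dbo);
}

// Depthwise application of the frozen 3x3 kernel bank with reflective
// borders: each input channel yields n_k response channels, ordered
// channel-major / kernel-minor.
// [[Rcpp::export(name = ".cpp_frozen_fw")]]
NumericVector cpp_frozen_fw(NumericVector x, NumericVector kerns) {
  IntegerVector dx = dims_of(x), dk = dims_of(kerns);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int nk = dk[2];
  const arma::uword L = (arma::uword)H * W;

  arma::imat map = build_map(H, W, 3, 3, 1, 1, 1, 1, H, W);
  arma::mat Wf(kerns.begin(), 9, nk, false, true);
  NumericVector out((R_xlen_t)L * C * nk * N);
  out.attr("dim") = IntegerVector::create(H, W, C * nk, N);

  arma::mat cols(9, L);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      gather(x.begin() + (R_xlen_t)L * (c + (R_xlen_t)C * n), H * W, 1, map, cols);
      arma::mat Y = cols.t() * Wf; // L x nk
      for (int k = 0; k < nk; ++k) {
        std::copy(Y.colptr(k), Y.colptr(k) + L,
                  out.begin() + (R_xlen_t)L * ((c * nk + k) + (R_xlen_t)C * nk * n));
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_frozen_bw")]]
NumericVector cpp_frozen_bw(NumericVector dy, NumericVector kerns,
                            int H, int W, int C, int N) {
  IntegerVector dk = dims_of(kerns);
  const int nk = dk[2];
  const arma::uword L = (arma::uword)H * W;

  arma::imat map = build_map(H, W, 3, 3, 1, 1, 1, 1, H, W);
  arma::mat Wf(kerns.begin(), 9, nk, false, true);
  NumericVector dxo((R_xlen_t)L * C * N);
  dxo.attr("dim") = IntegerVector::create(H, W, C, N);

  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      arma::mat dyv(const_cast<double*>(
                        dy.begin() + (R_xlen_t)L * ((R_xlen_t)c * nk + (R_xlen_t)C * nk * n)),
                    L, nk, false, true);
      arma::mat dcols = Wf * dyv.t(); // 9 x L
      scatter(dxo.begin() + (R_xlen_t)L * (c + (R_xlen_t)C * n), H * W, 1, map, dcols);
    }
  }
  return dxo;
}
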