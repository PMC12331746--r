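// 3D convolution kernels (im2col + BLAS matmul via Armadillo).
//
// Tensor layout matches the R side: dim (H, W, T, C, N), H fastest.
// Weight layout: dim (kh, kw, kt, Cin, Cout). Temporal stride is always 1;
// spatial stride, padding and dilation are general.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int n, int k, int s, int p, int d) {
  return (n + 2 * p - (d * (k - 1) + 1)) / s + 1;
}

// Build the im2col matrix for one (sample, output-time) slab.
static void im2col_slab(const double* x, int H, int W, int T, int C,
                        long long n_off, int t2,
                        int kh, int kw, int kt,
                        int H2, int W2,
                        int sh, int sw,
                        int ph, int pw, int pt,
                        int dh, int dw, int dt,
                        arma::mat& col) {
  const int P = H2 * W2;
  col.zeros();
  for (int ci = 0; ci < C; ++ci) {
    for (int kti = 0; kti < kt; ++kti) {
      int t = t2 - pt + kti * dt;
      if (t < 0 || t >= T) continue;
      long long base_ct = n_off + (long long)(ci) * T * W * H +
                          (long long)t * W * H;
      for (int kwi = 0; kwi < kw; ++kwi) {
        for (int khi = 0; khi < kh; ++khi) {
          int k = khi + kh * (kwi + kw * (kti + kt * ci));
          double* colk = col.colptr(0) + k; // row k, stride = col.n_rows
          for (int w2 = 0; w2 < W2; ++w2) {
            int w = w2 * sw - pw + kwi * dw;
            if (w < 0 || w >= W) continue;
            long long base = base_ct + (long long)w * H;
            for (int h2 = 0; h2 < H2; ++h2) {
              int h = h2 * sh - ph + khi * dh;
              if (h < 0 || h >= H) continue;
              col.at(k, h2 + H2 * w2) = x[base + h];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv3d_fw_cpp(NumericVector x, IntegerVector xdim,
                            NumericVector w, IntegerVector wdim,
                            NumericVector bias,
                            int sh, int sw,
                            int ph, int pw, int pt,
                            int dh, int dw, int dt) {
  const int H = xdim[0], W = xdim[1], T = xdim[2], C = xdim[3], N = xdim[4];
  const int kh = wdim[0], kw = wdim[1], kt = wdim[2];
  const int Cin = wdim[3], Cout = wdim[4];
  if (Cin != C) stop("conv3d: channel mismatch (%d vs %d)", Cin, C);
  const int H2 = out_size(H, kh, sh, ph, dh);
  const int W2 = out_size(W, kw, sw, pw, dw);
  const int T2 = out_size(T, kt, 1, pt, dt);
  const int K = kh * kw * kt * Cin;
  const int P = H2 * W2;

  // weights as (Cout x K)
  arma::mat Wm(Cout, K);
  {
    const double* wp = w.begin();
    for (int co = 0; co < Cout; ++co)
      for (int k = 0; k < K; ++k)
        Wm.at(co, k) = wp[k + (long long)K * co];
  }

  NumericVector out((long long)H2 * W2 * T2 * Cout * N);
  double* op = out.begin();
  arma::mat col(K, P);
  const double* xp = x.begin();
  const bool has_bias = bias.size() == Cout;

  for (int n = 0; n < N; ++n) {
    long long n_off = (long long)n * C * T * W * H;
    for (int t2 = 0; t2 < T2; ++t2) {
      im2col_slab(xp, H, W, T, C, n_off, t2, kh, kw, kt, H2, W2,
                  sh, sw, ph, pw, pt, dh, dw, dt, col);
      arma::mat O = Wm * col; // (Cout x P)
      for (int co = 0; co < Cout; ++co) {
        long long base = (long long)H2 * W2 *
          (t2 + (long long)T2 * (co + (long long)Cout * n));
        const double b = has_bias ? bias[co] : 0.0;
        for (int p = 0; p < P; ++p) op[base + p] = O.at(co, p) + b;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H2, W2, T2, Cout, N);
  return out;
}

// [[Rcpp::export]]
List conv3d_bw_cpp(NumericVector x, IntegerVector xdim,
                   NumericVector w, IntegerVector wdim,
                   NumericVector gout,
                   int sh, int sw,
                   int ph, int pw, int pt,
                   int dh, int dw, int dt,
                   bool need_gx, bool need_gw) {
  const int H = xdim[0], W = xdim[1], T = xdim[2], C = xdim[3], N = xdim[4];
  const int kh = wdim[0], kw = wdim[1], kt = wdim[2];
  const int Cin = wdim[3], Cout = wdim[4];
  const int H2 = out_size(H, kh, sh, ph, dh);
  const int W2 = out_size(W, kw, sw, pw, dw);
  const int T2 = out_size(T, kt, 1, pt, dt);
  const int K = kh * kw * kt * Cin;
  const int P = H2 * W2;

  arma::mat Wm(Cout, K);
  {
    const double* wp = w.begin();
    for (int co = 0; co < Cout; ++co)
      for (int k = 0; k < K; ++k)
        Wm.at(co, k) = wp[k + (long long)K * co];
  }

  NumericVector gx(need_gx ? x.size() : 0);
  arma::mat gW(Cout, K, arma::fill::zeros);
  arma::mat col(K, P);
  arma::mat Gm(Cout, P);
  const double* xp = x.begin();
  const double* gp = gout.begin();
  double* gxp = gx.begin();

  for (int n = 0; n < N; ++n) {
    long long n_off = (long long)n * C * T * W * H;
    for (int t2 = 0; t2 < T2; ++t2) {
      for (int co = 0; co < Cout; ++co) {
        long long base = (long long)H2 * W2 *
          (t2 + (long long)T2 * (co + (long long)Cout * n));
        for (int p = 0; p < P; ++p) Gm.at(co, p) = gp[base + p];
      }
      if (need_gw) {
        im2col_slab(xp, H, W, T, C, n_off, t2, kh, kw, kt, H2, W2,
                    sh, sw, ph, pw, pt, dh, dw, dt, col);
        gW += Gm * col.t();
      }
      if (need_gx) {
        arma::mat gcol = Wm.t() * Gm; // (K x P), scatter-add (col2im)
        for (int ci = 0; ci < C; ++ci) {
          for (int kti = 0; kti < kt; ++kti) {
            int t = t2 - pt + kti * dt;
            if (t < 0 || t >= T) continue;
            long long base_ct = n_off + (long long)(ci) * T * W * H +
                                (long long)t * W * H;
            for (int kwi = 0; kwi < kw; ++kwi) {
              for (int khi = 0; khi < kh; ++khi) {
                int k = khi + kh * (kwi + kw * (kti + kt * ci));
                for (int w2 = 0; w2 < W2; ++w2) {
                  int ww = w2 * sw - pw + kwi * dw;
                  if (ww < 0 || ww >= W) continue;
                  long long base = base_ct + (long long)ww * H;
                  for (int h2 = 0; h2 < H2; ++h2) {
                    int hh = h2 * sh - ph + khi * dh;
                    if (hh < 0 || hh >= H) continue;
                    gxp[base + hh] += gcol.at(k, h2 + H2 * w2);
                  }
                }
              }
            }
          }
        }
      }
    }
  }

  NumericVector gw_out((long long)K * Cout);
  if (need_gw) {
    double* gwp = gw_out.begin();
    for (int co = 0; co < Cout; ++co)
      for (int k = 0; k < K; ++k)
        gwp[k + (long long)K * co] = gW.at(co, k);
    gw_out.attr("dim") = IntegerVector::create(kh, kw, kt, Cin, Cout);
  }
  if (need_gx) gx.attr("dim") = xdim;
  return List::create(_["gx"] = gx, _["gw"] = gw_out);
}

#ifdef __GLIBC__
#include <malloc.h>
#endif

// Return freed heap pages to the OS (large transient conv buffers would
// otherwise accumulate as resident memory).
// [[Rcpp::export]]
void mem_trim_cpp() {
#ifdef __GLIBC__
  malloc_trim(0);
#endif
}

// Pin the malloc mmap threshold so multi-megabyte activation and im2col
// buffers are always mmapped and returned to the OS on free, instead of
// fragmenting the brk heap as glibc adapts its threshold upward.
// [[Rcpp::export]]
void mem_tune_cpp() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 1 << 20);
  mallopt(M_TRIM_THRESHOLD, 1 << 20);
#endif
}
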