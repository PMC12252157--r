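// Hot inner kernels of the CNN engine: im2col/col2im for 3x3
// same-padding convolutions and 2x2/stride-2 max-pooling, on activations
// stored as (N*H*H) x C matrices with row index = n*H*H + x*H + y
// (column-major within each image). Offset order matches the R side:
// k = 0..8 with dy = k %% 3 - 1 (fastest), dx = k / 3 - 1.

#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& X, int H, int N) {
  const int C = X.ncol();
  const int HW = H * H;
  const int rows = N * HW;
  NumericMatrix P(rows, 9 * C);
  const double* px = REAL(X);
  double* pp = REAL(P);
  for (int k = 0; k < 9; ++k) {
    const int dy = k % 3 - 1, dx = k / 3 - 1;
    const int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
    const int run = y1 - y0;
    if (run <= 0) continue;
    for (int c = 0; c < C; ++c) {
      const double* src = px + (size_t)c * rows;
      double* dst = pp + (size_t)(k * C + c) * rows;
      for (int n = 0; n < N; ++n) {
        const int base = n * HW;
        for (int x = 0; x < H; ++x) {
          const int xx = x + dx;
          if (xx < 0 || xx >= H) continue;
          std::memcpy(dst + base + x * H + y0,
                      src + base + xx * H + y0 + dy,
                      run * sizeof(double));
        }
      }
    }
  }
  return P;
}

// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& dP, int H, int N, int C) {
  const int HW = H * H;
  const int rows = N * HW;
  NumericMatrix dX(rows, C);
  const double* pp = REAL(dP);
  double* px = REAL(dX);
  for (int k = 0; k < 9; ++k) {
    const int dy = k % 3 - 1, dx = k / 3 - 1;
    const int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
    if (y1 - y0 <= 0) continue;
    for (int c = 0; c < C; ++c) {
      const double* src = pp + (size_t)(k * C + c) * rows;
      double* dst = px + (size_t)c * rows;
      for (int n = 0; n < N; ++n) {
        const int base = n * HW;
        for (int x = 0; x < H; ++x) {
          const int xx = x + dx;
          if (xx < 0 || xx >= H) continue;
          const double* s = src + base + x * H + y0;
          double* d = dst + base + xx * H + y0 + dy;
          for (int y = 0; y < y1 - y0; ++y) d[y] += s[y];
        }
      }
    }
  }
  return dX;
}

// [[Rcpp::export]]
List cpp_pool_fwd(const NumericMatrix& A, int H, int N) {
  const int C = A.ncol();
  const int H2 = H / 2;
  const int HW = H * H, HW2 = H2 * H2;
  const int rows_out = N * HW2;
  NumericMatrix out(rows_out, C);
  IntegerMatrix win(rows_out, C);
  const double* pa = REAL(A);
  double* po = REAL(out);
  int* pw = INTEGER(win);
  for (int c = 0; c < C; ++c) {
    const double* src = pa + (size_t)c * (size_t)(N * HW);
    double* dst = po + (size_t)c * rows_out;
    int* wv = pw + (size_t)c * rows_out;
    for (int n = 0; n < N; ++n) {
      const int bi = n * HW, bo = n * HW2;
      for (int x2 = 0; x2 < H2; ++x2) {
        for (int y2 = 0; y2 < H2; ++y2) {
          const int i0 = bi + (2 * x2) * H + 2 * y2;
          const int i1 = bi + (2 * x2 + 1) * H + 2 * y2;
          double best = src[i0]; int wk = 0;
          if (src[i0 + 1] > best) { best = src[i0 + 1]; wk = 1; }
          if (src[i1] > best) { best = src[i1]; wk = 2; }
          if (src[i1 + 1] > best) { best = src[i1 + 1]; wk = 3; }
          dst[bo + x2 * H2 + y2] = best;
          wv[bo + x2 * H2 + y2] = wk;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["win"] = win);
}

// [[Rcpp::export]]
NumericMatrix cpp_pool_bwd(const NumericMatrix& dOut, const IntegerMatrix& win,
                           int H, int N) {
  const int C = dOut.ncol();
  const int H2 = H / 2;
  const int HW = H * H, HW2 = H2 * H2;
  NumericMatrix dA(N * HW, C);
  const double* pd = REAL(dOut);
  const int* pw = INTEGER(win);
  double* pa = REAL(dA);
  for (int c = 0; c < C; ++c) {
    const double* src = pd + (size_t)c * (size_t)(N * HW2);
    const int* wv = pw + (size_t)c * (size_t)(N * HW2);
    double* dst = pa + (size_t)c * (size_t)(N * HW);
    for (int n = 0; n < N; ++n) {
      const int bi = n * HW, bo = n * HW2;
      for (int x2 = 0; x2 < H2; ++x2) {
        for (int y2 = 0; y2 < H2; ++y2) {
          const int o = bo + x2 * H2 + y2;
          const int wk = wv[o];
          const int dy = wk & 1, dx = wk >> 1;
          dst[bi + (2 * x2 + dx) * H + 2 * y2 + dy] = src[o];
        }
      }
    }
  }
  return dA;
}

// Fused batchnorm + ReLU forward: out = max(0, (Z - m) * ivar * g + b),
// per channel c. Batch statistics are computed by the caller.
// [[Rcpp::export]]
NumericMatrix cpp_bn_relu_fwd(const NumericMatrix& Z, const NumericVector& g,
                              const NumericVector& b, const NumericVector& m,
                              const NumericVector& ivar) {
  const int n = Z.nrow(), C = Z.ncol();
  NumericMatrix out(n, C);
  const double* pz = REAL(Z);
  double* po = REAL(out);
  for (int c = 0; c < C; ++c) {
    const double sc = ivar[c] * g[c];
    const double off = b[c] - m[c] * sc;
    const double* z = pz + (size_t)c * n;
    double* o = po + (size_t)c * n;
    for (int i = 0; i < n; ++i) {
      const double v = z[i] * sc + off;
      o[i] = v > 0 ? v : 0;
    }
  }
  return out;
}

// Fused ReLU-mask + batchnorm backward. dA is the gradient at the ReLU
// output; out the forward activations (for the mask); Z the pre-BN
// inputs (xhat is recomputed from Z, m, ivar).
// Returns dX (gradient at Z), dg, db.
// [[Rcpp::export]]
List cpp_bn_relu_bwd(const NumericMatrix& dA, const NumericMatrix& out,
                     const NumericMatrix& Z, const NumericVector& g,
                     const NumericVector& m, const NumericVector& ivar) {
  const int n = dA.nrow(), C = dA.ncol();
  NumericMatrix dX(n, C);
  NumericVector dg(C), db(C);
  const double* pd = REAL(dA);
  const double* po = REAL(out);
  const double* pz = REAL(Z);
  double* px = REAL(dX);
  for (int c = 0; c < C; ++c) {
    const double* d = pd + (size_t)c * n;
    const double* o = po + (size_t)c * n;
    const double* z = pz + (size_t)c * n;
    double* x = px + (size_t)c * n;
    const double mc = m[c], iv = ivar[c];
    double s1 = 0, s2 = 0;
    for (int i = 0; i < n; ++i) {
      const double dy = o[i] > 0 ? d[i] : 0;
      s1 += dy;
      s2 += dy * (z[i] - mc) * iv;
    }
    const double a1 = s1 / n, a2 = s2 / n;
    const double sc = g[c] * iv;
    for (int i = 0; i < n; ++i) {
      const double dy = o[i] > 0 ? d[i] : 0;
      x[i] = sc * (dy - a1 - (z[i] - mc) * iv * a2);
    }
    dg[c] = s2;
    db[c] = s1;
  }
  return List::create(_["dX"] = dX, _["dg"] = dg, _["db"] = db);
}
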