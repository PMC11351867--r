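// Low-level numerical kernels: 3x3 same-padding convolution (im2col + BLAS
// gemm) with exact gradients, 2x2 max-pooling, nearest-neighbour upsampling,
// and a separable exact Euclidean distance transform with anisotropic
// spacing. Tensors are dense double arrays in channel-first (C,H,W,B) layout.
#include <RcppArmadillo.h>
#include <cstring>
#include <limits>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Unfold a (C,H,W,B) array into the (9C x HWB) im2col matrix for a 3x3
// kernel with zero padding 1. Row order within a column is (c, ky, kx)
// with c fastest, matching the (Cout x 9C) weight layout used in R.
static arma::mat im2col3(const double* x, int C, int H, int W, int B) {
  const int Hp = H + 2, Wp = W + 2;
  std::vector<double> xp((size_t)C * Hp * Wp * B, 0.0);
  for (int b = 0; b < B; ++b)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const double* src = x + (size_t)C * (h + (size_t)H * (w + (size_t)W * b));
        double* dst = xp.data() +
          (size_t)C * ((h + 1) + (size_t)Hp * ((w + 1) + (size_t)Wp * b));
        std::memcpy(dst, src, sizeof(double) * C);
      }
  arma::mat Xc(9 * C, (size_t)H * W * B);
  double* out = Xc.memptr();
  size_t col = 0;
  for (int b = 0; b < B; ++b)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h, ++col) {
        double* dst = out + col * (size_t)(9 * C);
        for (int kx = 0; kx < 3; ++kx)
          for (int ky = 0; ky < 3; ++ky) {
            const double* src = xp.data() +
              (size_t)C * ((h + ky) + (size_t)Hp * ((w + kx) + (size_t)Wp * b));
            std::memcpy(dst + (size_t)C * (ky + 3 * kx), src, sizeof(double) * C);
          }
      }
  return Xc;
}

// [[Rcpp::export]]
NumericVector cpp_conv3_fwd(NumericVector x, IntegerVector dims,
                            NumericMatrix Wm, NumericVector bias) {
  const int C = dims[0], H = dims[1], W = dims[2], B = dims[3];
  const int Cout = Wm.nrow();
  arma::mat Xc = im2col3(REAL(x), C, H, W, B);
  arma::mat Wa(Wm.begin(), Cout, Wm.ncol(), false);
  arma::mat Y = Wa * Xc;
  arma::vec bv(bias.begin(), bias.size(), false);
  Y.each_col() += bv;
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(Cout, H, W, B);
  return out;
}

// [[Rcpp::export]]
List cpp_conv3_bwd(NumericVector x, IntegerVector dims, NumericMatrix Wm,
                   NumericVector dy) {
  const int C = dims[0], H = dims[1], W = dims[2], B = dims[3];
  const int Cout = Wm.nrow();
  const size_t N = (size_t)H * W * B;
  arma::mat Xc = im2col3(REAL(x), C, H, W, B);
  arma::mat dY(REAL(dy), Cout, N, false);
  arma::mat Wa(Wm.begin(), Cout, Wm.ncol(), false);
  arma::mat dW = dY * Xc.t();
  arma::vec db = arma::sum(dY, 1);
  arma::mat dXc = Wa.t() * dY;  // (9C x N)
  const int Hp = H + 2, Wp = W + 2;
  std::vector<double> dxp((size_t)C * Hp * Wp * B, 0.0);
  const double* src0 = dXc.memptr();
  size_t col = 0;
  for (int b = 0; b < B; ++b)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h, ++col) {
        const double* scol = src0 + col * (size_t)(9 * C);
        for (int kx = 0; kx < 3; ++kx)
          for (int ky = 0; ky < 3; ++ky) {
            double* dst = dxp.data() +
              (size_t)C * ((h + ky) + (size_t)Hp * ((w + kx) + (size_t)Wp * b));
            const double* s = scol + (size_t)C * (ky + 3 * kx);
            for (int c = 0; c < C; ++c) dst[c] += s[c];
          }
      }
  NumericVector dx((R_xlen_t)((size_t)C * H * W * B));
  for (int b = 0; b < B; ++b)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        double* dst = REAL(dx) + (size_t)C * (h + (size_t)H * (w + (size_t)W * b));
        const double* src = dxp.data() +
          (size_t)C * ((h + 1) + (size_t)Hp * ((w + 1) + (size_t)Wp * b));
        std::memcpy(dst, src, sizeof(double) * C);
      }
  dx.attr("dim") = dims;
  NumericMatrix dWout(Cout, Wm.ncol());
  std::memcpy(dWout.begin(), dW.memptr(), sizeof(double) * dW.n_elem);
  return List::create(_["dx"] = dx, _["dW"] = dWout,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// 2x2 max pooling with stride 2; records argmax offset (ky + 2*kx in 0..3).
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x, IntegerVector dims) {
  const int C = dims[0], H = dims[1], W = dims[2], B = dims[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)((size_t)C * Ho * Wo * B));
  IntegerVector which((R_xlen_t)((size_t)C * Ho * Wo * B));
  const double* xp = REAL(x);
  double* yp = REAL(y);
  int* wp = INTEGER(which);
  for (int b = 0; b < B; ++b)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        size_t oc = (size_t)C * (h + (size_t)Ho * (w + (size_t)Wo * b));
        for (int c = 0; c < C; ++c) {
          double best = -1e300; int arg = 0;
          for (int kx = 0; kx < 2; ++kx)
            for (int ky = 0; ky < 2; ++ky) {
              double v = xp[c + (size_t)C * ((2 * h + ky) +
                            (size_t)H * ((2 * w + kx) + (size_t)W * b))];
              if (v > best) { best = v; arg = ky + 2 * kx; }
            }
          yp[oc + c] = best;
          wp[oc + c] = arg;
        }
      }
  y.attr("dim") = IntegerVector::create(C, Ho, Wo, B);
  which.attr("dim") = IntegerVector::create(C, Ho, Wo, B);
  return List::create(_["y"] = y, _["which"] = which);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector dy, IntegerVector which,
                               IntegerVector dims_in) {
  const int C = dims_in[0], H = dims_in[1], W = dims_in[2], B = dims_in[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector dx((R_xlen_t)((size_t)C * H * W * B));
  const double* dyp = REAL(dy);
  const int* wp = INTEGER(which);
  double* dxp = REAL(dx);
  for (int b = 0; b < B; ++b)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        size_t oc = (size_t)C * (h + (size_t)Ho * (w + (size_t)Wo * b));
        for (int c = 0; c < C; ++c) {
          int arg = wp[oc + c];
          int ky = arg % 2, kx = arg / 2;
          dxp[c + (size_t)C * ((2 * h + ky) +
               (size_t)H * ((2 * w + kx) + (size_t)W * b))] += dyp[oc + c];
        }
      }
  dx.attr("dim") = dims_in;
  return dx;
}

// Nearest-neighbour 2x upsampling and its adjoint (2x2 block sum).
// [[Rcpp::export]]
NumericVector cpp_upsample2(NumericVector x, IntegerVector dims) {
  const int C = dims[0], H = dims[1], W = dims[2], B = dims[3];
  NumericVector y((R_xlen_t)((size_t)C * 4 * H * W * B));
  const double* xp = REAL(x);
  double* yp = REAL(y);
  const int Ho = 2 * H, Wo = 2 * W;
  for (int b = 0; b < B; ++b)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        const double* src = xp + (size_t)C * ((h / 2) + (size_t)H * ((w / 2) + (size_t)W * b));
        double* dst = yp + (size_t)C * (h + (size_t)Ho * (w + (size_t)Wo * b));
        std::memcpy(dst, src, sizeof(double) * C);
      }
  y.attr("dim") = IntegerVector::create(C, Ho, Wo, B);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_downsum2(NumericVector dy, IntegerVector dims_out) {
  // dims_out is the (C,H,W,B) of the *coarse* grid being reduced to.
  const int C = dims_out[0], H = dims_out[1], W = dims_out[2], B = dims_out[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector dx((R_xlen_t)((size_t)C * H * W * B));
  const double* dyp = REAL(dy);
  double* dxp = REAL(dx);
  for (int b = 0; b < B; ++b)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        const double* src = dyp + (size_t)C * (h + (size_t)Ho * (w + (size_t)Wo * b));
        double* dst = dxp + (size_t)C * ((h / 2) + (size_t)H * ((w / 2) + (size_t)W * b));
        for (int c = 0; c < C; ++c) dst[c] += src[c];
      }
  dx.attr("dim") = dims_out;
  return dx;
}

// ---- exact Euclidean distance transform (Felzenszwalb & Huttenlocher) ----
static const double DT_INF = 1e30;

static void dt1d(const double* f, double* d, int n, double s2) {
  // f holds large-but-finite DT_INF for non-seed sites so parabola
  // subtractions stay finite; the envelope sentinels must be true
  // infinities or an intersection point could fall below the left sentinel
  // and underflow the stack.
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -inf;
  z[1] = inf;
  for (int q = 1; q < n; ++q) {
    double fq = f[q] + s2 * q * q;
    double s;
    while (true) {
      int p = v[k];
      s = (fq - (f[p] + s2 * p * p)) / (2.0 * s2 * (q - p));
      if (s <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = inf;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    d[q] = s2 * (q - p) * (q - p) + f[p];
  }
}

// Squared Euclidean distance (physical units) from every pixel of an HxW
// grid to the nearest seed pixel. spacing = (row, col) in mm.
// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(LogicalMatrix seed, double sp_row, double sp_col) {
  const int H = seed.nrow(), W = seed.ncol();
  NumericMatrix d(H, W);
  std::vector<double> buf(std::max(H, W)), out(std::max(H, W));
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      d(h, w) = seed(h, w) ? 0.0 : DT_INF;
  // pass 1: along columns (row index, spacing sp_row)
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) buf[h] = d(h, w);
    dt1d(buf.data(), out.data(), H, sp_row * sp_row);
    for (int h = 0; h < H; ++h) d(h, w) = out[h];
  }
  // pass 2: along rows (col index, spacing sp_col)
  for (int h = 0; h < H; ++h) {
    for (int w = 0; w < W; ++w) buf[w] = d(h, w);
    dt1d(buf.data(), out.data(), W, sp_col * sp_col);
    for (int w = 0; w < W; ++w) d(h, w) = out[w];
  }
  return d;
}
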