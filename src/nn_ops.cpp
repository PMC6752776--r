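// Minimal CNN kernels: im2col-based 2-D convolution and pooling with full
// backward passes. Layout matches R column-major arrays [H, W, C] and
// kernels [kh, kw, C, K]. All loops are single-threaded and deterministic.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::cube;
using arma::mat;

static int out_size(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

static mat im2col(const cube& x, int kh, int kw, int sh, int sw, int ph,
                  int pw, int Ho, int Wo) {
  const int C = x.n_slices, H = x.n_rows, W = x.n_cols;
  mat col(kh * kw * C, Ho * Wo, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int q = 0; q < kw; ++q)
      for (int p = 0; p < kh; ++p) {
        const int r = c * kh * kw + q * kh + p;
        for (int j = 0; j < Wo; ++j) {
          const int xj = j * sw + q - pw;
          if (xj < 0 || xj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int xi = i * sh + p - ph;
            if (xi < 0 || xi >= H) continue;
            col(r, j * Ho + i) = x(xi, xj, c);
          }
        }
      }
  return col;
}

static mat weight_mat(const NumericVector& w, int kh, int kw, int C, int K) {
  mat Wm(K, kh * kw * C);
  for (int k = 0; k < K; ++k)
    for (int c = 0; c < C; ++c)
      for (int q = 0; q < kw; ++q)
        for (int p = 0; p < kh; ++p)
          Wm(k, c * kh * kw + q * kh + p) =
              w[p + kh * (q + kw * (c + C * k))];
  return Wm;
}

// [[Rcpp::export(name = ".nnConvForward")]]
NumericVector nn_conv_forward(NumericVector x, NumericVector w,
                              NumericVector b, int sh, int sw, int ph,
                              int pw) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int kh = wd[0], kw = wd[1], K = wd[3];
  const int Ho = out_size(H, kh, sh, ph), Wo = out_size(W, kw, sw, pw);
  cube xc(x.begin(), H, W, C, false);
  mat col = im2col(xc, kh, kw, sh, sw, ph, pw, Ho, Wo);
  mat Y = weight_mat(w, kh, kw, C, K) * col;
  Y.each_col() += mat(b.begin(), K, 1, false);
  NumericVector y(Ho * Wo * K);
  y.attr("dim") = IntegerVector::create(Ho, Wo, K);
  for (int k = 0; k < K; ++k)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        y[i + Ho * (j + Wo * k)] = Y(k, j * Ho + i);
  return y;
}

// [[Rcpp::export(name = ".nnConvBackward")]]
List nn_conv_backward(NumericVector x, NumericVector w, NumericVector dy,
                      int sh, int sw, int ph, int pw) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"),
                yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int kh = wd[0], kw = wd[1], K = wd[3];
  const int Ho = yd[0], Wo = yd[1];
  cube xc(x.begin(), H, W, C, false);
  mat col = im2col(xc, kh, kw, sh, sw, ph, pw, Ho, Wo);
  mat dY(K, Ho * Wo);
  for (int k = 0; k < K; ++k)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        dY(k, j * Ho + i) = dy[i + Ho * (j + Wo * k)];
  mat Wm = weight_mat(w, kh, kw, C, K);
  mat dWm = dY * col.t();
  mat dcol = Wm.t() * dY;

  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  for (int k = 0; k < K; ++k)
    for (int c = 0; c < C; ++c)
      for (int q = 0; q < kw; ++q)
        for (int p = 0; p < kh; ++p)
          dw[p + kh * (q + kw * (c + C * k))] =
              dWm(k, c * kh * kw + q * kh + p);
  NumericVector db(K);
  for (int k = 0; k < K; ++k) db[k] = arma::accu(dY.row(k));

  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  cube dxc(dx.begin(), H, W, C, false);
  for (int c = 0; c < C; ++c)
    for (int q = 0; q < kw; ++q)
      for (int p = 0; p < kh; ++p) {
        const int r = c * kh * kw + q * kh + p;
        for (int j = 0; j < Wo; ++j) {
          const int xj = j * sw + q - pw;
          if (xj < 0 || xj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int xi = i * sh + p - ph;
            if (xi < 0 || xi >= H) continue;
            dxc(xi, xj, c) += dcol(r, j * Ho + i);
          }
        }
      }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export(name = ".nnPoolForward")]]
List nn_pool_forward(NumericVector x, int kh, int kw, int sh, int sw, int ph,
                     int pw, bool maxpool) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int Ho = out_size(H, kh, sh, ph), Wo = out_size(W, kw, sw, pw);
  cube xc(x.begin(), H, W, C, false);
  NumericVector y(Ho * Wo * C);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  IntegerVector idx(maxpool ? Ho * Wo * C : 0);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double best = -1e300, acc = 0.0;
        int besti = -1, nvalid = 0;
        for (int q = 0; q < kw; ++q) {
          const int xj = j * sw + q - pw;
          if (xj < 0 || xj >= W) continue;
          for (int p = 0; p < kh; ++p) {
            const int xi = i * sh + p - ph;
            if (xi < 0 || xi >= H) continue;
            const double v = xc(xi, xj, c);
            ++nvalid;
            acc += v;
            if (v > best) { best = v; besti = xi + H * (xj + W * c); }
          }
        }
        const int o = i + Ho * (j + Wo * c);
        if (maxpool) {
          y[o] = best;
          idx[o] = besti;  // 0-based linear index into x
        } else {
          y[o] = acc / nvalid;
        }
      }
  if (maxpool) return List::create(_["y"] = y, _["idx"] = idx);
  return List::create(_["y"] = y);
}

// [[Rcpp::export(name = ".nnMaxPoolBackward")]]
NumericVector nn_maxpool_backward(NumericVector dy, IntegerVector idx,
                                  IntegerVector xdim) {
  const int n = xdim[0] * xdim[1] * xdim[2];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  for (int o = 0; o < dy.size(); ++o) dx[idx[o]] += dy[o];
  return dx;
}

// [[Rcpp::export(name = ".nnAvgPoolBackward")]]
NumericVector nn_avgpool_backward(NumericVector dy, IntegerVector xdim,
                                  int kh, int kw, int sh, int sw, int ph,
                                  int pw) {
  IntegerVector yd = dy.attr("dim");
  const int H = xdim[0], W = xdim[1], C = xdim[2];
  const int Ho = yd[0], Wo = yd[1];
  NumericVector dx(H * W * C);
  dx.attr("dim") = xdim;
  cube dxc(dx.begin(), H, W, C, false);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        int nvalid = 0;
        for (int q = 0; q < kw; ++q) {
          const int xj = j * sw + q - pw;
          if (xj < 0 || xj >= W) continue;
          for (int p = 0; p < kh; ++p) {
            const int xi = i * sh + p - ph;
            if (xi >= 0 && xi < H) ++nvalid;
          }
        }
        const double g = dy[i + Ho * (j + Wo * c)] / nvalid;
        for (int q = 0; q < kw; ++q) {
          const int xj = j * sw + q - pw;
          if (xj < 0 || xj >= W) continue;
          for (int p = 0; p < kh; ++p) {
            const int xi = i * sh + p - ph;
            if (xi >= 0 && xi < H) dxc(xi, xj, c) += g;
          }
        }
      }
  return dx;
}
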