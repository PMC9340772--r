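#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Dense tensors are column-major R arrays, images (H, W, C, N),
// conv kernels (kh, kw, Cin, Cout). Stride is fixed at 1; pooling is 2x2/2.

static void im2col(const double* X, int H, int W, int C,
                   int kh, int kw, int pad, arma::mat& cols) {
  const int Ho = H + 2 * pad - kh + 1;
  const int Wo = W + 2 * pad - kw + 1;
  for (int c = 0; c < C; ++c)
    for (int dw = 0; dw < kw; ++dw)
      for (int dh = 0; dh < kh; ++dh) {
        const int r = dh + kh * (dw + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo + dw - pad;
          const bool wok = (wi >= 0 && wi < W);
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho + dh - pad;
            cols(r, ho + Ho * wo) =
              (wok && hi >= 0 && hi < H) ? X[hi + H * (wi + (size_t)W * c)] : 0.0;
          }
        }
      }
}

static void col2im_add(const arma::mat& cols, int H, int W, int C,
                       int kh, int kw, int pad, double* dX) {
  const int Ho = H + 2 * pad - kh + 1;
  const int Wo = W + 2 * pad - kw + 1;
  for (int c = 0; c < C; ++c)
    for (int dw = 0; dw < kw; ++dw)
      for (int dh = 0; dh < kh; ++dh) {
        const int r = dh + kh * (dw + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo + dw - pad;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho + dh - pad;
            if (hi < 0 || hi >= H) continue;
            dX[hi + H * (wi + (size_t)W * c)] += cols(r, ho + Ho * wo);
          }
        }
      }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector X, NumericVector Wt, NumericVector b,
                         int pad) {
  IntegerVector xd = X.attr("dim"), wd = Wt.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Co = wd[3];
  if (Cin != C) stop("channel mismatch");
  const int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;
  const int K = kh * kw * Cin, P = Ho * Wo;
  arma::mat Wm(Wt.begin(), K, Co, false, true);
  arma::vec bv(b.begin(), Co, false, true);
  NumericVector Y((size_t)P * Co * N);
  Y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  arma::mat cols(K, P);
  for (int n = 0; n < N; ++n) {
    im2col(&X[(size_t)H * W * C * n], H, W, C, kh, kw, pad, cols);
    arma::mat M = Wm.t() * cols;   // Co x P
    M.each_col() += bv;
    double* Yp = &Y[(size_t)P * Co * n];
    for (int o = 0; o < Co; ++o)
      for (int p = 0; p < P; ++p)
        Yp[p + (size_t)P * o] = M(o, p);
  }
  return Y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector X, NumericVector Wt, NumericVector dY, int pad) {
  IntegerVector xd = X.attr("dim"), wd = Wt.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Co = wd[3];
  const int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;
  const int K = kh * kw * Cin, P = Ho * Wo;
  arma::mat Wm(Wt.begin(), K, Co, false, true);
  NumericVector dX((size_t)H * W * C * N);
  dX.attr("dim") = xd;
  NumericVector dW((size_t)K * Co);
  dW.attr("dim") = wd;
  NumericVector db(Co);
  arma::mat dWm(dW.begin(), K, Co, false, true);
  arma::vec dbv(db.begin(), Co, false, true);
  arma::mat cols(K, P), dM(Co, P);
  for (int n = 0; n < N; ++n) {
    const double* dYp = &dY[(size_t)P * Co * n];
    for (int o = 0; o < Co; ++o)
      for (int p = 0; p < P; ++p)
        dM(o, p) = dYp[p + (size_t)P * o];
    im2col(&X[(size_t)H * W * C * n], H, W, C, kh, kw, pad, cols);
    dWm += cols * dM.t();
    dbv += arma::sum(dM, 1);
    arma::mat dcols = Wm * dM;     // K x P
    col2im_add(dcols, H, W, C, kh, kw, pad, &dX[(size_t)H * W * C * n]);
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
List maxpool2_fwd(NumericVector X) {
  IntegerVector xd = X.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("maxpool2 requires even spatial dims");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector Y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  Y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = Y.attr("dim");
  size_t q = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho, ++q) {
          double best = -INFINITY; size_t bi = 0;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh) {
              const size_t i = base + (2 * ho + dh) + (size_t)H * (2 * wo + dw);
              if (X[i] > best) { best = X[i]; bi = i; }
            }
          Y[q] = best; idx[q] = (int)bi;
        }
    }
  return List::create(_["Y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd(IntegerVector idx, NumericVector dY,
                           IntegerVector xdim) {
  NumericVector dX((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dX.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dY.size(); ++i) dX[idx[i]] += dY[i];
  return dX;
}
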