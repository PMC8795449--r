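// Compute kernels for the sequence VAE layers.
//
// Activations are 4-d arrays (H, W, B, C): alignment length x alphabet x
// batch x channels, column-major as R stores them. 3x3 same-padding
// convolutions are realized as im2col + one BLAS GEMM; the im2col column
// order (di fastest, then dj, then input channel) matches the column-major
// layout of the (3, 3, Cin, Cout) kernel array, so kernels reshape to a
// (9*Cin, Cout) matrix in place. The im2col matrix is returned to R so the
// backward pass can reuse it for the weight-gradient GEMM.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Fill one im2col column for shift (di, dj) of channel c.
static void gatherShift(const double* Xc, double* dst, int H, int W, int B,
                        int di, int dj) {
  const int h0 = std::max(0, -di), h1 = std::min(H, H - di);
  for (int b = 0; b < B; ++b) {
    for (int w = 0; w < W; ++w) {
      const int ws = w + dj;
      double* out = dst + ((long)b * W + w) * H;
      if (ws < 0 || ws >= W) {
        std::memset(out, 0, sizeof(double) * H);
        continue;
      }
      const double* src = Xc + ((long)b * W + ws) * H;
      if (h0 > 0) out[0] = 0.0;
      if (h1 < H) out[H - 1] = 0.0;
      std::memcpy(out + h0, src + h0 + di, sizeof(double) * (h1 - h0));
    }
  }
}

static NumericMatrix im2col3x3(const double* X, int H, int W, int B, int C) {
  const long n = (long)H * W * B;
  NumericMatrix col(n, 9 * C);
  for (int c = 0; c < C; ++c) {
    const double* Xc = X + (long)c * n;
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di)
        gatherShift(Xc, &col(0, (di + 1) + 3 * (dj + 1) + 9 * c),
                    H, W, B, di, dj);
  }
  return col;
}

// [[Rcpp::export(name = ".cppConvForward")]]
List cppConvForward(NumericVector X, NumericVector K, NumericVector bias,
                    IntegerVector dims, int cOut) {
  int H = dims[0], W = dims[1], B = dims[2], C = dims[3];
  const long n = (long)H * W * B;
  NumericMatrix col = im2col3x3(X.begin(), H, W, B, C);
  arma::mat colM(col.begin(), n, 9 * C, false, true);
  arma::mat Km(K.begin(), 9 * C, cOut, false, true);
  arma::mat Y = colM * Km;
  Y.each_row() += arma::rowvec(bias.begin(), cOut);
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(H, W, B, cOut);
  return List::create(_["out"] = out, _["col"] = col);
}

// [[Rcpp::export(name = ".cppConvBackward")]]
List cppConvBackward(NumericMatrix col, NumericVector K, NumericVector dY,
                     IntegerVector dims, int cOut) {
  int H = dims[0], W = dims[1], B = dims[2], C = dims[3];
  const long n = (long)H * W * B;
  arma::mat colM(col.begin(), n, 9 * C, false, true);
  arma::mat dYm(dY.begin(), n, cOut, false, true);
  arma::mat Km(K.begin(), 9 * C, cOut, false, true);
  arma::mat dK = colM.t() * dYm;
  arma::rowvec db = arma::sum(dYm, 0);
  arma::mat dcol = dYm * Km.t();
  // col2im: scatter-add the gathered gradients back onto the input grid
  NumericVector dX((R_xlen_t)n * C);
  dX.attr("dim") = IntegerVector::create(H, W, B, C);
  for (int c = 0; c < C; ++c) {
    double* dXc = dX.begin() + (long)c * n;
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const double* src = dcol.colptr((di + 1) + 3 * (dj + 1) + 9 * c);
        const int h0 = std::max(0, -di), h1 = std::min(H, H - di);
        for (int b = 0; b < B; ++b) {
          for (int w = 0; w < W; ++w) {
            const int ws = w + dj;
            if (ws < 0 || ws >= W) continue;
            double* dst = dXc + ((long)b * W + ws) * H + di;
            const double* s = src + ((long)b * W + w) * H;
            for (int h = h0; h < h1; ++h) dst[h] += s[h];
          }
        }
      }
    }
  }
  NumericVector dKout(dK.begin(), dK.end());
  dKout.attr("dim") = IntegerVector::create(3, 3, C, cOut);
  return List::create(_["dX"] = dX, _["dW"] = dKout,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export(name = ".cppElu")]]
NumericVector cppElu(NumericVector X) {
  NumericVector Y = clone(X);
  for (R_xlen_t i = 0; i < Y.size(); ++i)
    if (Y[i] < 0) Y[i] = std::expm1(Y[i]);
  return Y;
}

// [[Rcpp::export(name = ".cppEluBackward")]]
NumericVector cppEluBackward(NumericVector dY, NumericVector Y) {
  NumericVector dX = clone(dY);
  for (R_xlen_t i = 0; i < dX.size(); ++i)
    if (Y[i] < 0) dX[i] *= Y[i] + 1.0;  // d/dx elu = exp(x) = y + 1 for x<0
  return dX;
}

// [[Rcpp::export(name = ".cppPoolForward")]]
List cppPoolForward(NumericVector X, IntegerVector dims) {
  int H = dims[0];
  R_xlen_t nOut = X.size() / 2;
  NumericVector Y(nOut);
  LogicalVector top(nOut);
  for (R_xlen_t i = 0; i < nOut; ++i) {
    double a = X[2 * i], b = X[2 * i + 1];
    top[i] = a >= b;
    Y[i] = top[i] ? a : b;
  }
  Y.attr("dim") = IntegerVector::create(H / 2, dims[1], dims[2], dims[3]);
  return List::create(_["out"] = Y, _["top"] = top);
}

// [[Rcpp::export(name = ".cppPoolBackward")]]
NumericVector cppPoolBackward(NumericVector dY, LogicalVector top,
                              IntegerVector dims) {
  NumericVector dX((R_xlen_t)2 * dY.size());
  for (R_xlen_t i = 0; i < dY.size(); ++i)
    dX[2 * i + (top[i] ? 0 : 1)] = dY[i];
  dX.attr("dim") = dims;
  return dX;
}

// [[Rcpp::export(name = ".cppUpsampleForward")]]
NumericVector cppUpsampleForward(NumericVector X, IntegerVector dims) {
  int H = dims[0];
  NumericVector Y((R_xlen_t)2 * X.size());
  for (R_xlen_t i = 0; i < X.size(); ++i) {
    Y[2 * i] = X[i];
    Y[2 * i + 1] = X[i];
  }
  Y.attr("dim") = IntegerVector::create(2 * H, dims[1], dims[2], dims[3]);
  return Y;
}

// [[Rcpp::export(name = ".cppUpsampleBackward")]]
NumericVector cppUpsampleBackward(NumericVector dY, IntegerVector dims) {
  NumericVector dX(dY.size() / 2);
  for (R_xlen_t i = 0; i < dX.size(); ++i)
    dX[i] = dY[2 * i] + dY[2 * i + 1];
  dX.attr("dim") = IntegerVector::create(dims[0] / 2, dims[1], dims[2],
                                         dims[3]);
  return dX;
}
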