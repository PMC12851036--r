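#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Unrolls a [C, T, B] signal array into a (C*k) x (T*B) matrix for
// length-preserving 1-D convolution as a single GEMM (zero padding,
// odd kernel centered).
// [[Rcpp::export(name = ".im2col1d")]]
NumericMatrix im2col1d(NumericVector x, int C, int T, int B, int k) {
  int p = (k - 1) / 2;
  NumericMatrix out(C * k, T * B);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < T; ++t) {
      double* col = op + (size_t)(b * (size_t)T + t) * (size_t)(C * k);
      for (int j = 0; j < k; ++j) {
        int ts = t + j - p;
        if (ts < 0 || ts >= T) {
          for (int c = 0; c < C; ++c) col[j * C + c] = 0.0;
        } else {
          const double* src = xp + ((size_t)b * T + ts) * (size_t)C;
          for (int c = 0; c < C; ++c) col[j * C + c] = src[c];
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col1d: scatter-adds column gradients back onto the
// [C, T, B] input array.
// [[Rcpp::export(name = ".col2im1d")]]
NumericVector col2im1d(NumericMatrix dxcol, int C, int T, int B, int k) {
  int p = (k - 1) / 2;
  NumericVector out((size_t)C * T * B);  // zero-initialized
  double* op = out.begin();
  const double* dp = dxcol.begin();
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < T; ++t) {
      const double* col = dp + (size_t)(b * (size_t)T + t) * (size_t)(C * k);
      for (int j = 0; j < k; ++j) {
        int ts = t + j - p;
        if (ts < 0 || ts >= T) continue;
        double* dst = op + ((size_t)b * T + ts) * (size_t)C;
        for (int c = 0; c < C; ++c) dst[c] += col[j * C + c];
      }
    }
  }
  out.attr("dim") = IntegerVector::create(C, T, B);
  return out;
}

// Kernel-3, stride-1, length-preserving max pooling over the time
// dimension of a [C, T, B] array; returns the pooled values and the
// flat index of each window's argmax for the backward pass.
// [[Rcpp::export(name = ".maxpool3C")]]
List maxpool3C(NumericVector x, int C, int T, int B) {
  NumericVector y((size_t)C * T * B);
  IntegerVector am((size_t)C * T * B);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ap = am.begin();
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < T; ++t) {
      size_t base = ((size_t)b * T + t) * C;
      for (int c = 0; c < C; ++c) {
        double best = xp[base + c];
        size_t bi = base + c;
        if (t > 0) {
          double v = xp[base - C + c];
          if (v > best) { best = v; bi = base - C + c; }
        }
        if (t < T - 1) {
          double v = xp[base + C + c];
          if (v > best) { best = v; bi = base + C + c; }
        }
        yp[base + c] = best;
        ap[base + c] = (int)bi;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(C, T, B);
  return List::create(Named("y") = y, Named("argmax") = am);
}

// [[Rcpp::export(name = ".maxpool3BackwardC")]]
NumericVector maxpool3BackwardC(NumericVector dy, IntegerVector am,
                                int C, int T, int B) {
  NumericVector out((size_t)C * T * B);
  double* op = out.begin();
  const double* dp = dy.begin();
  const int* ap = am.begin();
  size_t n = (size_t)C * T * B;
  for (size_t i = 0; i < n; ++i) op[ap[i]] += dp[i];
  out.attr("dim") = IntegerVector::create(C, T, B);
  return out;
}

// Unconstrained dynamic-time-warping alignment cost with
// absolute-difference local cost and match/insert/delete steps.
// [[Rcpp::export(name = ".dtwCostC")]]
double dtwCostC(NumericVector a, NumericVector b) {
  int n = a.size(), m = b.size();
  std::vector<double> prev(m + 1, R_PosInf), cur(m + 1, R_PosInf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = R_PosInf;
    for (int j = 1; j <= m; ++j) {
      double c = std::fabs(a[i - 1] - b[j - 1]);
      double best = std::min(prev[j], std::min(cur[j - 1], prev[j - 1]));
      cur[j] = c + best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}
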