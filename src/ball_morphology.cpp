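// Grayscale morphology with a non-flat (ball) structuring element, the
// kernel of rolling-ball background estimation. Pixels outside the image
// domain are ignored (not padded), which keeps the opening anti-extensive
// for the symmetric ball element.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix ball_erode(NumericMatrix img, IntegerVector di,
                         IntegerVector dj, NumericVector z) {
  const int H = img.nrow(), W = img.ncol(), K = di.size();
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double m = R_PosInf;
      for (int k = 0; k < K; ++k) {
        const int ii = i + di[k], jj = j + dj[k];
        if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
        const double v = img(ii, jj) - z[k];
        if (v < m) m = v;
      }
      out(i, j) = m;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix ball_dilate(NumericMatrix img, IntegerVector di,
                          IntegerVector dj, NumericVector z) {
  const int H = img.nrow(), W = img.ncol(), K = di.size();
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double m = R_NegInf;
      for (int k = 0; k < K; ++k) {
        const int ii = i + di[k], jj = j + dj[k];
        if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
        const double v = img(ii, jj) + z[k];
        if (v > m) m = v;
      }
      out(i, j) = m;
    }
  }
  return out;
}
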