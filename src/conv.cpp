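// Gather/scatter kernels for the dilated 3x3 convolutions: im2col and its
// transpose. Feature maps are (batch*H*W) x channels matrices; idx holds
// one-based source pixel indices per 3x3 offset, 0 marking zero padding.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".im2col_cpp")]]
NumericMatrix im2col_cpp(NumericMatrix X, IntegerMatrix idx) {
  const int n = X.nrow(), C = X.ncol();
  NumericMatrix out(n, 9 * C);
  for (int ch = 0; ch < C; ch++) {
    const double* xc = &X(0, ch);
    for (int o = 0; o < 9; o++) {
      double* oc = &out(0, ch * 9 + o);
      const int* ic = &idx(0, o);
      for (int p = 0; p < n; p++) {
        const int s = ic[p];
        oc[p] = s > 0 ? xc[s - 1] : 0.0;
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".col2im_cpp")]]
NumericMatrix col2im_cpp(NumericMatrix dcols, IntegerMatrix idx, int C) {
  const int n = dcols.nrow();
  NumericMatrix dX(n, C);
  for (int ch = 0; ch < C; ch++) {
    double* dc = &dX(0, ch);
    for (int o = 0; o < 9; o++) {
      const double* src = &dcols(0, ch * 9 + o);
      const int* ic = &idx(0, o);
      for (int p = 0; p < n; p++) {
        const int s = ic[p];
        if (s > 0) dc[s - 1] += src[p];
      }
    }
  }
  return dX;
}
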