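// Inner kernels of the autodiff tape: depthwise 3x3 convolution,
// cross-window max fusion, and row gather/scatter-add.  Index arguments are
// 1-based (R convention).

#include <Rcpp.h>
using namespace Rcpp;

// depthwise 3x3 conv forward: xp (Np x C) padded tokens, w (9 x C),
// idx (N x 9) padded-token index per output token and kernel offset
// [[Rcpp::export]]
NumericMatrix cpp_dw_fwd(const NumericMatrix& xp, const NumericMatrix& w,
                         const IntegerMatrix& idx) {
  const int n = idx.nrow(), C = xp.ncol();
  NumericMatrix out(n, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &xp(0, c);
    double* oc = &out(0, c);
    for (int o = 0; o < 9; ++o) {
      const double wv = w(o, c);
      if (wv == 0.0) continue;
      const int* ic = &idx(0, o);
      for (int i = 0; i < n; ++i) oc[i] += wv * xc[ic[i] - 1];
    }
  }
  return out;
}

// depthwise 3x3 conv backward: returns gx (Np x C) and gw (9 x C)
// [[Rcpp::export]]
List cpp_dw_bwd(const NumericMatrix& g, const NumericMatrix& xp,
                const NumericMatrix& w, const IntegerMatrix& idx) {
  const int n = idx.nrow(), C = xp.ncol(), np = xp.nrow();
  NumericMatrix gx(np, C), gw(9, C);
  for (int c = 0; c < C; ++c) {
    const double* gc = &g(0, c);
    const double* xc = &xp(0, c);
    double* gxc = &gx(0, c);
    for (int o = 0; o < 9; ++o) {
      const double wv = w(o, c);
      const int* ic = &idx(0, o);
      double acc = 0.0;
      for (int i = 0; i < n; ++i) {
        const int t = ic[i] - 1;
        gxc[t] += wv * gc[i];
        acc += gc[i] * xc[t];
      }
      gw(o, c) = acc;
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

// cross-window max fusion forward: x ((Mi*M2) x C) rows ordered position-
// fastest, valid (M2 x Mi); returns fused (M2 x C) and argmax window
// (M2 x C, 0 where no window is valid)
// [[Rcpp::export]]
List cpp_fuse_max_fwd(const NumericMatrix& x, const LogicalMatrix& valid,
                      int Mi, int M2) {
  const int C = x.ncol();
  NumericMatrix out(M2, C);
  IntegerMatrix argw(M2, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    for (int m = 0; m < M2; ++m) {
      double best = R_NegInf;
      int bj = 0;
      for (int j = 0; j < Mi; ++j) {
        if (!valid(m, j)) continue;
        const double v = xc[j * M2 + m];
        if (v > best) { best = v; bj = j + 1; }
      }
      out(m, c) = bj ? best : 0.0;
      argw(m, c) = bj;
    }
  }
  return List::create(_["out"] = out, _["argw"] = argw);
}

// max fusion backward: routes the gradient to the argmax window
// [[Rcpp::export]]
NumericMatrix cpp_fuse_max_bwd(const NumericMatrix& g, const IntegerMatrix& argw,
                               int Mi, int M2) {
  const int C = g.ncol();
  NumericMatrix gx(Mi * M2, C);
  for (int c = 0; c < C; ++c) {
    for (int m = 0; m < M2; ++m) {
      const int j = argw(m, c);
      if (j > 0) gx((j - 1) * M2 + m, c) = g(m, c);
    }
  }
  return gx;
}

// row gather: out = x[idx, ]
// [[Rcpp::export]]
NumericMatrix cpp_gather_rows(const NumericMatrix& x, const IntegerVector& idx) {
  const int n = idx.size(), C = x.ncol();
  NumericMatrix out(n, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    double* oc = &out(0, c);
    for (int i = 0; i < n; ++i) oc[i] = xc[idx[i] - 1];
  }
  return out;
}

// scatter-add rows: out (nout x C), out[idx[i], ] += g[i, ]
// [[Rcpp::export]]
NumericMatrix cpp_scatter_add_rows(const NumericMatrix& g, const IntegerVector& idx,
                                   int nout) {
  const int n = idx.size(), C = g.ncol();
  NumericMatrix out(nout, C);
  for (int c = 0; c < C; ++c) {
    const double* gc = &g(0, c);
    double* oc = &out(0, c);
    for (int i = 0; i < n; ++i) oc[idx[i] - 1] += gc[i];
  }
  return out;
}
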