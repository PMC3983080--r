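/* Hierarchical piecewise-multilinear sparse-grid evaluation kernel. */

#include <R.h>
#include <Rinternals.h>

SEXP awmpc_sg_eval(SEXP levels, SEXP coords, SEXP surplus, SEXP x) {
  int n = Rf_nrows(coords), d = Rf_ncols(coords);
  double *lv = REAL(levels), *cd = REAL(coords), *w = REAL(surplus),
    *xq = REAL(x);
  double acc = 0.0;
  for (int i = 0; i < n; i++) {
    double b = 1.0;
    for (int j = 0; j < d; j++) {
      double l = lv[i + (R_xlen_t) n * j];
      double xn = cd[i + (R_xlen_t) n * j];
      double q = xq[j], bj;
      if (l == 0.0) {
        bj = 1.0;
      } else if (l == 1.0) {
        bj = (xn == 0.0) ? (1.0 - 2.0 * q) : (2.0 * q - 1.0);
        if (bj < 0.0) bj = 0.0;
      } else {
        double h = ldexp(1.0, (int) l);   /* 2^l */
        bj = 1.0 - h * fabs(q - xn);
        if (bj < 0.0) bj = 0.0;
      }
      if (bj == 0.0) { b = 0.0; break; }
      b *= bj;
    }
    acc += w[i] * b;
  }
  return Rf_ScalarReal(acc);
}
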