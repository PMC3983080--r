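/* Compiled dynamics for the miniature three-member signaling-cascade bank.
 * State vectors are augmented with the two standing input concentrations
 * (last two entries, held constant by the integrator; boluses add to them
 * between integration segments). Parameter order must match the R-side
 * .params_A / .params_B / .params_C vectors. */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

static double hill01(double c, double K) { return c / (c + K); }

/* ---- member A: mass-action cascade with receptor decay ---- */
/* params: r1 Rb a1 b1 a2 b2 a3 b3 K1 e1 K2 e2 (12)
 * states: R X1 X1p X2 X2p X3 X3p c1 c2 (9) */
static double pA[12];
void awmpc_initA(void (*odeparms)(int *, double *)) {
  int n = 12;
  odeparms(&n, pA);
}
void awmpc_derivsA(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip) {
  double a3eff = pA[6] * (1.0 - pA[11] * hill01(y[8], pA[10]));
  double b3eff = pA[7] * (1.0 - pA[9] * hill01(y[7], pA[8]));
  double dX1p = pA[2] * y[0] * y[1] - pA[3] * y[2];
  double dX2p = pA[4] * y[2] * y[3] - pA[5] * y[4];
  double dX3p = a3eff * y[4] * y[5] - b3eff * y[6];
  ydot[0] = -pA[0] * (y[0] - pA[1]);
  ydot[1] = -dX1p; ydot[2] = dX1p;
  ydot[3] = -dX2p; ydot[4] = dX2p;
  ydot[5] = -dX3p; ydot[6] = dX3p;
  ydot[7] = 0.0; ydot[8] = 0.0;
}

/* ---- member B: mass-action cascade with feedback loops ---- */
/* params: a1 b1 a2 b2 fp a3 b3 kp dp gP K1 e1 K2 e2 (14)
 * states: X1 X1p X2 X2p X3 X3p P c1 c2 (9) */
static double pB[14];
void awmpc_initB(void (*odeparms)(int *, double *)) {
  int n = 14;
  odeparms(&n, pB);
}
void awmpc_derivsB(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip) {
  double a3eff = pB[5] * (1.0 - pB[13] * hill01(y[8], pB[12]));
  double dinh = 1.0 - pB[11] * hill01(y[7], pB[10]);
  double b3eff = pB[6] * (1.0 + pB[9] * y[6]) * dinh;
  double a2eff = pB[2] * (1.0 + pB[4] * y[5]);
  double dX1p = pB[0] * y[0] - pB[1] * y[1];
  double dX2p = a2eff * y[1] * y[2] - pB[3] * y[3];
  double dX3p = a3eff * y[3] * y[4] - b3eff * y[5];
  ydot[0] = -dX1p; ydot[1] = dX1p;
  ydot[2] = -dX2p; ydot[3] = dX2p;
  ydot[4] = -dX3p; ydot[5] = dX3p;
  ydot[6] = pB[7] * y[5] - pB[8] * y[6];
  ydot[7] = 0.0; ydot[8] = 0.0;
}

/* ---- member C: normalized Hill-type dynamics on [0,1] states ---- */
/* params: tau1 tauv Kv nv tau2 K12 n12 kf K23 n23 kd K1 e1 K2 e2 (15)
 * states: x1 v x2 x3 c1 c2 (6) */
static double pC[15];
void awmpc_initC(void (*odeparms)(int *, double *)) {
  int n = 15;
  odeparms(&n, pC);
}
static double nhill(double x, double K, double n) {
  double xn = pow(x, n), Kn = pow(K, n);
  if (x <= 0.0) return 0.0;
  return (xn / (xn + Kn)) * (1.0 + Kn);
}
void awmpc_derivsC(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip) {
  double finh = 1.0 - pC[14] * hill01(y[5], pC[13]);
  double dinh = 1.0 - pC[12] * hill01(y[4], pC[11]);
  ydot[0] = ((1.0 - y[1]) - y[0]) / pC[0];
  ydot[1] = (nhill(y[0], pC[2], pC[3]) - y[1]) / pC[1];
  ydot[2] = (nhill(y[0], pC[5], pC[6]) - y[2]) / pC[4];
  ydot[3] = pC[7] * nhill(y[2], pC[8], pC[9]) * finh * (1.0 - y[3]) -
    pC[10] * dinh * y[3];
  ydot[4] = 0.0; ydot[5] = 0.0;
}

SEXP awmpc_sg_eval(SEXP levels, SEXP coords, SEXP surplus, SEXP x);

static const R_CallMethodDef CallEntries[] = {
  {"awmpc_sg_eval", (DL_FUNC) &awmpc_sg_eval, 4},
  {NULL, NULL, 0}
};

static const R_CMethodDef CEntries[] = {
  {"awmpc_derivsA", (DL_FUNC) &awmpc_derivsA, 6},
  {"awmpc_derivsB", (DL_FUNC) &awmpc_derivsB, 6},
  {"awmpc_derivsC", (DL_FUNC) &awmpc_derivsC, 6},
  {NULL, NULL, 0}
};

void R_init_awmpc(DllInfo *dll) {
  R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
  R_useDynamicSymbols(dll, TRUE);
}
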