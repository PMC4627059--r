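/* Compiled mass-action right-hand side and steady-state root function for
 * deSolve's compiled-model interface. The current network (reactant
 * indices, rate constants, stoichiometry triplets) is staged from R with
 * evosig_set_network() before each integration; solvers then call
 * evosig_derivs() / evosig_root() by symbol name. Single-threaded use, as
 * in deSolve itself.
 */
#include <R.h>
#include <Rinternals.h>
#include <stdlib.h>
#include <string.h>

static int n_rx = 0, n_sp = 0, nnz = 0;
static int *r1 = NULL, *r2 = NULL;        /* 1-based; r2 = 0 if absent */
static double *rate = NULL;
static int *si = NULL, *sj = NULL;        /* stoichiometry triplets, 1-based */
static double *sv = NULL;
static double crit_atol = 1e-9, crit_tol = 1e-6;
static double *flux = NULL, *ydot_buf = NULL;

static void free_all(void) {
  free(r1); free(r2); free(rate); free(si); free(sj); free(sv);
  free(flux); free(ydot_buf);
  r1 = r2 = si = sj = NULL;
  rate = sv = flux = ydot_buf = NULL;
  n_rx = n_sp = nnz = 0;
}

SEXP evosig_set_network(SEXP R1, SEXP R2, SEXP RATE, SEXP SI, SEXP SJ,
                        SEXP SV, SEXP NSP, SEXP ATOL, SEXP SSTOL) {
  free_all();
  n_rx = LENGTH(R1);
  nnz = LENGTH(SI);
  n_sp = INTEGER(NSP)[0];
  crit_atol = REAL(ATOL)[0];
  crit_tol = REAL(SSTOL)[0];
  if (n_rx > 0) {
    r1 = (int *) malloc(n_rx * sizeof(int));
    r2 = (int *) malloc(n_rx * sizeof(int));
    rate = (double *) malloc(n_rx * sizeof(double));
    flux = (double *) malloc(n_rx * sizeof(double));
    memcpy(r1, INTEGER(R1), n_rx * sizeof(int));
    memcpy(r2, INTEGER(R2), n_rx * sizeof(int));
    memcpy(rate, REAL(RATE), n_rx * sizeof(double));
  }
  if (nnz > 0) {
    si = (int *) malloc(nnz * sizeof(int));
    sj = (int *) malloc(nnz * sizeof(int));
    sv = (double *) malloc(nnz * sizeof(double));
    memcpy(si, INTEGER(SI), nnz * sizeof(int));
    memcpy(sj, INTEGER(SJ), nnz * sizeof(int));
    memcpy(sv, REAL(SV), nnz * sizeof(double));
  }
  if (n_sp > 0) ydot_buf = (double *) malloc(n_sp * sizeof(double));
  return R_NilValue;
}

static void mass_action_rhs(const double *y, double *ydot) {
  int i;
  for (i = 0; i < n_sp; i++) ydot[i] = 0.0;
  for (i = 0; i < n_rx; i++) {
    double v = rate[i] * y[r1[i] - 1];
    if (r2[i] > 0) v *= y[r2[i] - 1];
    flux[i] = v;
  }
  for (i = 0; i < nnz; i++) ydot[si[i] - 1] += sv[i] * flux[sj[i] - 1];
}

void evosig_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip) {
  (void) neq; (void) t; (void) yout; (void) ip;
  mass_action_rhs(y, ydot);
}

/* steady-state criterion: max_i |dy_i| / (atol + |y_i|) - ss_tol */
void evosig_root(int *neq, double *t, double *y, int *ng, double *gout,
                 double *out, int *ip) {
  (void) t; (void) ng; (void) out; (void) ip;
  int i, n = *neq;
  double m = 0.0;
  mass_action_rhs(y, ydot_buf);
  for (i = 0; i < n; i++) {
    double d = fabs(ydot_buf[i]) / (crit_atol + fabs(y[i]));
    if (d > m) m = d;
  }
  gout[0] = m - crit_tol;
}
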