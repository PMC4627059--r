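#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP evosig_set_network(SEXP R1, SEXP R2, SEXP RATE, SEXP SI, SEXP SJ,
                        SEXP SV, SEXP NSP, SEXP ATOL, SEXP SSTOL);
void evosig_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip);
void evosig_root(int *neq, double *t, double *y, int *ng, double *gout,
                 double *out, int *ip);

static const R_CallMethodDef call_entries[] = {
  {"evosig_set_network", (DL_FUNC) &evosig_set_network, 9},
  {NULL, NULL, 0}
};

static const R_CMethodDef c_entries[] = {
  {"evosig_derivs", (DL_FUNC) &evosig_derivs, 6},
  {"evosig_root",   (DL_FUNC) &evosig_root,   7},
  {NULL, NULL, 0}
};

void R_init_evosig(DllInfo *dll) {
  R_registerRoutines(dll, c_entries, call_entries, NULL, NULL);
  R_useDynamicSymbols(dll, FALSE);
}
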