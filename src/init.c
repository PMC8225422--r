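#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP hhnet_set_params(SEXP pars);
void hhnet_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip);

static const R_CallMethodDef call_entries[] = {
    {"hhnet_set_params", (DL_FUNC) &hhnet_set_params, 1},
    {NULL, NULL, 0}
};

/* registered as a .C routine so deSolve can resolve it by name */
static const R_CMethodDef c_entries[] = {
    {"hhnet_derivs", (DL_FUNC) &hhnet_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_plastinet(DllInfo *dll)
{
    R_registerRoutines(dll, c_entries, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
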