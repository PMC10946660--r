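#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void qslum_initmod(void (*odeparms)(int *, double *));
void qslum_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip);

static const R_CMethodDef CEntries[] = {
    {"qslum_initmod", (DL_FUNC) &qslum_initmod, 1},
    {"qslum_derivs",  (DL_FUNC) &qslum_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_qslum(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
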