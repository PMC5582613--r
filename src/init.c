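#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void meiqx_initmod(void (*odeparms)(int *, double *));
void meiqx_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip);

static const R_CMethodDef CEntries[] = {
    {"meiqx_initmod", (DL_FUNC) &meiqx_initmod, 1},
    {"meiqx_derivs",  (DL_FUNC) &meiqx_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_meiqxkin(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, FALSE);
}
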