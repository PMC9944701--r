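#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void pbpk_init(void (*odeparms)(int *, double *));
void pbpk_deriv(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip);

static const R_CMethodDef CEntries[] = {
    {"pbpk_init",  (DL_FUNC) &pbpk_init,  1},
    {"pbpk_deriv", (DL_FUNC) &pbpk_deriv, 6},
    {NULL, NULL, 0}
};

void R_init_tetrodose(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
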