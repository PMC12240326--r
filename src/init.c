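#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void reef_initmod(void (* odeparms)(int *, double *));
void reef_rhs(int *neq, double *t, double *y, double *ydot,
              double *yout, int *ip);

static const R_CMethodDef CEntries[] = {
    {"reef_initmod", (DL_FUNC) &reef_initmod, 1},
    {"reef_rhs",     (DL_FUNC) &reef_rhs,     6},
    {NULL, NULL, 0}
};

void R_init_reefherb(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
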