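#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_expm_action(SEXP L, SEXP t, SEXP m0);
SEXP C_cw_zvalues(SEXP sysv, SEXP offs, SEXP nut, SEXP dur);

static const R_CallMethodDef call_entries[] = {
    {"C_expm_action", (DL_FUNC) &C_expm_action, 3},
    {"C_cw_zvalues",  (DL_FUNC) &C_cw_zvalues,  4},
    {NULL, NULL, 0}
};

void R_init_destfit(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, TRUE);
}
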