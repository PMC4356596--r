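// Native routine registration.  The .Call entries are the Rcpp attribute
// exports (declared in RcppExports.cpp); the .C entries are the deSolve
// derivative/Jacobian callbacks, which must be registered so that deSolve
// can look them up by name.

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

extern SEXP _mtorswitch_rn_rhs_cpp(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);
extern SEXP _mtorswitch_rn_jac_cpp(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);
extern SEXP _mtorswitch_rn_set_system(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);
extern SEXP _mtorswitch_rn_set_ramp(SEXP, SEXP, SEXP, SEXP, SEXP);

extern void rn_derivs(int *, double *, double *, double *, double *, int *);
extern void rn_jacobian(int *, double *, double *, int *, int *, double *,
                        int *, double *, int *);

static const R_CallMethodDef CallEntries[] = {
    {"_mtorswitch_rn_rhs_cpp", (DL_FUNC) &_mtorswitch_rn_rhs_cpp, 8},
    {"_mtorswitch_rn_jac_cpp", (DL_FUNC) &_mtorswitch_rn_jac_cpp, 8},
    {"_mtorswitch_rn_set_system", (DL_FUNC) &_mtorswitch_rn_set_system, 7},
    {"_mtorswitch_rn_set_ramp", (DL_FUNC) &_mtorswitch_rn_set_ramp, 5},
    {NULL, NULL, 0}
};

static const R_CMethodDef CEntries[] = {
    {"rn_derivs", (DL_FUNC) &rn_derivs, 6},
    {"rn_jacobian", (DL_FUNC) &rn_jacobian, 9},
    {NULL, NULL, 0}
};

void R_init_mtorswitch(DllInfo *dll) {
    R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
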