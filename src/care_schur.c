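/* Ordered real Schur decomposition of a Hamiltonian matrix via LAPACK dgees.
 *
 * The continuous algebraic Riccati equation F'V + VF - VGV + H = 0 is solved
 * by the Schur method: form Phi = [[F, -G], [-H, -F']], compute a real Schur
 * factorization U' Phi U = S with the eigenvalues of negative real part
 * ordered to the leading block, and read the stabilizing solution off the
 * invariant subspace as V = U21 U11^{-1}.  This file only performs the
 * ordered factorization; the back-solve and diagnostics live in R.
 */
#define USE_FC_LEN_T
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Lapack.h>
#ifndef FCONE
# define FCONE
#endif

typedef int (*dgees_sel)(const double *, const double *);

extern void F77_NAME(dgees)(const char *jobvs, const char *sort,
    dgees_sel select, const int *n, double *a, const int *lda, int *sdim,
    double *wr, double *wi, double *vs, const int *ldvs, double *work,
    const int *lwork, int *bwork, int *info FCLEN FCLEN);

/* select eigenvalues with strictly negative real part for the leading block */
static int select_stable(const double *wr, const double *wi)
{
    (void) wi;
    return *wr < 0.0;
}

/* Returns list(vs = orthogonal Schur vectors, sdim = #selected,
 *              wr, wi = eigenvalue parts, info = LAPACK status). */
SEXP C_schur_ordered(SEXP mat)
{
    if (!isReal(mat) || !isMatrix(mat))
        error("'mat' must be a numeric matrix");
    int n = nrows(mat);
    if (ncols(mat) != n)
        error("'mat' must be square");

    SEXP a = PROTECT(duplicate(mat));
    SEXP vs = PROTECT(allocMatrix(REALSXP, n, n));
    SEXP wr = PROTECT(allocVector(REALSXP, n));
    SEXP wi = PROTECT(allocVector(REALSXP, n));
    int sdim = 0, info = 0, lwork = -1;
    int *bwork = (int *) R_alloc(n, sizeof(int));
    double wkopt = 0.0;

    /* workspace query */
    F77_CALL(dgees)("V", "S", select_stable, &n, REAL(a), &n, &sdim,
                    REAL(wr), REAL(wi), REAL(vs), &n, &wkopt, &lwork,
                    bwork, &info FCONE FCONE);
    lwork = (int) wkopt;
    if (lwork < 3 * n) lwork = 3 * n;
    double *work = (double *) R_alloc(lwork, sizeof(double));

    F77_CALL(dgees)("V", "S", select_stable, &n, REAL(a), &n, &sdim,
                    REAL(wr), REAL(wi), REAL(vs), &n, work, &lwork,
                    bwork, &info FCONE FCONE);

    SEXP out = PROTECT(allocVector(VECSXP, 5));
    SEXP nms = PROTECT(allocVector(STRSXP, 5));
    SET_VECTOR_ELT(out, 0, vs);
    SET_VECTOR_ELT(out, 1, ScalarInteger(sdim));
    SET_VECTOR_ELT(out, 2, wr);
    SET_VECTOR_ELT(out, 3, wi);
    SET_VECTOR_ELT(out, 4, ScalarInteger(info));
    SET_STRING_ELT(nms, 0, mkChar("vs"));
    SET_STRING_ELT(nms, 1, mkChar("sdim"));
    SET_STRING_ELT(nms, 2, mkChar("wr"));
    SET_STRING_ELT(nms, 3, mkChar("wi"));
    SET_STRING_ELT(nms, 4, mkChar("info"));
    setAttrib(out, R_NamesSymbol, nms);
    UNPROTECT(6);
    return out;
}
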