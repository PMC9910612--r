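/* Dense matrix exponential (scaling-and-squaring, Pade order 13, Higham
 * 2005) acting on a state vector, plus a batched driver that evaluates a
 * continuous-wave Bloch-McConnell Z-spectrum: one 7x7 exponential per
 * saturation offset. The matrices are tiny, so plain triple loops beat any
 * BLAS dispatch overhead. */

#include <R.h>
#include <Rinternals.h>
#include <math.h>
#include <string.h>

/* C = A %*% B, all n x n column-major */
static void matmul(int n, const double *a, const double *b, double *c)
{
    for (int j = 0; j < n; j++)
        for (int i = 0; i < n; i++) {
            double s = 0.0;
            for (int k = 0; k < n; k++)
                s += a[i + k * n] * b[k + j * n];
            c[i + j * n] = s;
        }
}

/* solve A X = B in place (B overwritten with X, m right-hand sides) by LU
 * with partial pivoting; A is destroyed. Returns 0 on success. */
static int lu_solve(int n, double *a, double *b, int m)
{
    for (int k = 0; k < n; k++) {
        int p = k;
        double amax = fabs(a[k + k * n]);
        for (int i = k + 1; i < n; i++)
            if (fabs(a[i + k * n]) > amax) { amax = fabs(a[i + k * n]); p = i; }
        if (amax == 0.0) return 1;
        if (p != k) {
            for (int j = 0; j < n; j++) {
                double tmp = a[k + j * n]; a[k + j * n] = a[p + j * n];
                a[p + j * n] = tmp;
            }
            for (int j = 0; j < m; j++) {
                double tmp = b[k + j * n]; b[k + j * n] = b[p + j * n];
                b[p + j * n] = tmp;
            }
        }
        for (int i = k + 1; i < n; i++) {
            double f = a[i + k * n] / a[k + k * n];
            a[i + k * n] = f;
            for (int j = k + 1; j < n; j++)
                a[i + j * n] -= f * a[k + j * n];
        }
    }
    for (int j = 0; j < m; j++) {            /* forward substitution */
        for (int k = 0; k < n; k++)
            for (int i = k + 1; i < n; i++)
                b[i + j * n] -= a[i + k * n] * b[k + j * n];
        for (int k = n - 1; k >= 0; k--) {    /* back substitution */
            b[k + j * n] /= a[k + k * n];
            for (int i = 0; i < k; i++)
                b[i + j * n] -= a[i + k * n] * b[k + j * n];
        }
    }
    return 0;
}

static const double pade13[14] = {
    64764752532480000.0, 32382376266240000.0, 7771770303897600.0,
    1187353796428800.0, 129060195264000.0, 10559470521600.0, 670442572800.0,
    33522128640.0, 1323241920.0, 40840800.0, 960960.0, 16380.0, 182.0, 1.0
};

/* F <- expm(A); work must hold 8 n*n blocks. Returns 0 on success. */
static int expm_dense(int n, const double *a_in, double *f, double *work)
{
    int nn = n * n;
    double *A  = work;
    double *A2 = work + nn;
    double *A4 = work + 2 * nn;
    double *A6 = work + 3 * nn;
    double *U  = work + 4 * nn;
    double *V  = work + 5 * nn;
    double *W  = work + 6 * nn;
    double *W2 = work + 7 * nn;
    const double *b = pade13;

    memcpy(A, a_in, nn * sizeof(double));

    /* 1-norm for the scaling parameter */
    double nrm = 0.0;
    for (int j = 0; j < n; j++) {
        double cs = 0.0;
        for (int i = 0; i < n; i++) cs += fabs(A[i + j * n]);
        if (cs > nrm) nrm = cs;
    }
    int s = 0;
    const double theta13 = 5.371920351148152;
    if (nrm > theta13) {
        double l2 = log2(nrm / theta13);
        s = (int)ceil(l2);
        double scale = ldexp(1.0, -s); /* 2^-s */
        for (int i = 0; i < nn; i++) A[i] *= scale;
    }

    matmul(n, A, A, A2);
    matmul(n, A2, A2, A4);
    matmul(n, A2, A4, A6);

    /* W = b13*A6 + b11*A4 + b9*A2 ; W2 = A6*W + b7*A6 + b5*A4 + b3*A2 + b1*I
     * U = A * W2 */
    for (int i = 0; i < nn; i++)
        W[i] = b[13] * A6[i] + b[11] * A4[i] + b[9] * A2[i];
    matmul(n, A6, W, W2);
    for (int i = 0; i < nn; i++)
        W2[i] += b[7] * A6[i] + b[5] * A4[i] + b[3] * A2[i];
    for (int i = 0; i < n; i++) W2[i + i * n] += b[1];
    matmul(n, A, W2, U);

    /* V = A6*(b12*A6 + b10*A4 + b8*A2) + b6*A6 + b4*A4 + b2*A2 + b0*I */
    for (int i = 0; i < nn; i++)
        W[i] = b[12] * A6[i] + b[10] * A4[i] + b[8] * A2[i];
    matmul(n, A6, W, V);
    for (int i = 0; i < nn; i++)
        V[i] += b[6] * A6[i] + b[4] * A4[i] + b[2] * A2[i];
    for (int i = 0; i < n; i++) V[i + i * n] += b[0];

    /* solve (V - U) F = (V + U) */
    for (int i = 0; i < nn; i++) {
        f[i] = V[i] + U[i];
        W[i] = V[i] - U[i];
    }
    if (lu_solve(n, W, f, n)) return 1;

    for (int k = 0; k < s; k++) {
        matmul(n, f, f, W);
        memcpy(f, W, nn * sizeof(double));
    }
    return 0;
}

/* exp(L * t) %*% m0 for a square real L */
SEXP C_expm_action(SEXP Ls, SEXP ts, SEXP m0s)
{
    SEXP dim = getAttrib(Ls, R_DimSymbol);
    if (dim == R_NilValue || LENGTH(dim) != 2 ||
        INTEGER(dim)[0] != INTEGER(dim)[1])
        error("L must be a square matrix");
    int n = INTEGER(dim)[0];
    if (LENGTH(m0s) != n) error("M0 must have length %d", n);
    double t = asReal(ts);
    const double *L = REAL(Ls);
    const double *m0 = REAL(m0s);

    int nn = n * n;
    double *At = (double *) R_alloc(nn, sizeof(double));
    double *F  = (double *) R_alloc(nn, sizeof(double));
    double *wk = (double *) R_alloc(8 * nn, sizeof(double));
    for (int i = 0; i < nn; i++) At[i] = L[i] * t;
    if (expm_dense(n, At, F, wk))
        error("matrix exponential failed (singular Pade denominator)");

    SEXP out = PROTECT(allocVector(REALSXP, n));
    double *o = REAL(out);
    for (int i = 0; i < n; i++) {
        double sacc = 0.0;
        for (int k = 0; k < n; k++) sacc += F[i + k * n] * m0[k];
        o[i] = sacc;
    }
    UNPROTECT(1);
    return out;
}

/* Z-spectrum of the two-pool CW Bloch-McConnell system: for each
 * saturation offset, build the 7x7 augmented generator, propagate thermal
 * equilibrium for `duration`, and return MzA normalized by its equilibrium
 * value. sysv = (R1A, R2A, R1B, R2B, offsetA, offsetB, pB, kf, kb). */
SEXP C_cw_zvalues(SEXP sysv, SEXP offs, SEXP nut, SEXP dur)
{
    if (LENGTH(sysv) != 9) error("sysv must have length 9");
    const double *p = REAL(sysv);
    double R1A = p[0], R2A = p[1], R1B = p[2], R2B = p[3];
    double offA = p[4], offB = p[5], pB = p[6], kf = p[7], kb = p[8];
    double w1 = 2.0 * M_PI * asReal(nut);
    double t = asReal(dur);
    double meqA = 1.0 - pB, meqB = pB;
    int no = LENGTH(offs);
    const double *off = REAL(offs);

    const int n = 7, nn = 49;
    double L[49], F[49];
    double *wk = (double *) R_alloc(8 * nn, sizeof(double));
    double M0[7] = {0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 1.0};
    M0[2] = meqA; M0[5] = meqB;

    SEXP out = PROTECT(allocVector(REALSXP, no));
    double *z = REAL(out);

    for (int io = 0; io < no; io++) {
        double dA = 2.0 * M_PI * (offA - off[io]);
        double dB = 2.0 * M_PI * (offB - off[io]);
        memset(L, 0, sizeof(L));
        /* pool A block (rows/cols 0:2) */
        L[0 + 0 * n] = -R2A - kf; L[0 + 1 * n] = dA;
        L[1 + 0 * n] = -dA;       L[1 + 1 * n] = -R2A - kf;
        L[1 + 2 * n] = w1;
        L[2 + 1 * n] = -w1;       L[2 + 2 * n] = -R1A - kf;
        L[2 + 6 * n] = R1A * meqA;
        /* pool B block (rows/cols 3:5) */
        L[3 + 3 * n] = -R2B - kb; L[3 + 4 * n] = dB;
        L[4 + 3 * n] = -dB;       L[4 + 4 * n] = -R2B - kb;
        L[4 + 5 * n] = w1;
        L[5 + 4 * n] = -w1;       L[5 + 5 * n] = -R1B - kb;
        L[5 + 6 * n] = R1B * meqB;
        /* exchange off-diagonals */
        L[0 + 3 * n] = kb; L[1 + 4 * n] = kb; L[2 + 5 * n] = kb;
        L[3 + 0 * n] = kf; L[4 + 1 * n] = kf; L[5 + 2 * n] = kf;

        for (int i = 0; i < nn; i++) L[i] *= t;
        if (expm_dense(n, L, F, wk))
            error("matrix exponential failed at offset %g", off[io]);
        double mz = 0.0;
        for (int k = 0; k < n; k++) mz += F[2 + k * n] * M0[k];
        z[io] = mz / meqA;
    }
    UNPROTECT(1);
    return out;
}
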