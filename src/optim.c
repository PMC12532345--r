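/* Fused in-place optimizer kernels. The R level guarantees exclusive
 * ownership of the parameter/moment arrays passed here (networks are
 * deep-copied before a training loop touches them), so updating through
 * the data pointer is safe and avoids three full-size temporaries per
 * layer per step. */

#include <R.h>
#include <Rinternals.h>
#include <math.h>

/* Adam: updates w, m, v in place; t is the (already incremented) step. */
SEXP C_adam_step(SEXP W, SEXP M, SEXP V, SEXP G,
                 SEXP lr_, SEXP b1_, SEXP b2_, SEXP eps_, SEXP t_)
{
    R_xlen_t n = XLENGTH(W);
    double *w = REAL(W), *m = REAL(M), *v = REAL(V), *g = REAL(G);
    double lr = asReal(lr_), b1 = asReal(b1_), b2 = asReal(b2_);
    double eps = asReal(eps_);
    double t = asReal(t_);
    double c1 = 1.0 - pow(b1, t), c2 = 1.0 - pow(b2, t);
    for (R_xlen_t i = 0; i < n; i++) {
        m[i] = b1 * m[i] + (1.0 - b1) * g[i];
        v[i] = b2 * v[i] + (1.0 - b2) * g[i] * g[i];
        w[i] -= lr * (m[i] / c1) / (sqrt(v[i] / c2) + eps);
    }
    return R_NilValue;
}

/* Polyak averaging: target <- (1 - tau) * target + tau * source, in place. */
SEXP C_soft_update(SEXP T, SEXP S, SEXP tau_)
{
    R_xlen_t n = XLENGTH(T);
    double *t = REAL(T), *s = REAL(S);
    double tau = asReal(tau_);
    for (R_xlen_t i = 0; i < n; i++)
        t[i] = (1.0 - tau) * t[i] + tau * s[i];
    return R_NilValue;
}

/* add bias b to each column block of matrix Y [n x m], in place (Y is a
 * freshly allocated GEMM result owned by the caller) */
SEXP C_add_bias(SEXP Y, SEXP B)
{
    R_xlen_t n = nrows(Y);
    int m = ncols(Y);
    double *y = REAL(Y), *b = REAL(B);
    for (int j = 0; j < m; j++) {
        double bj = b[j];
        double *col = y + (R_xlen_t)j * n;
        for (R_xlen_t i = 0; i < n; i++) col[i] += bj;
    }
    return Y;
}

/* ReLU forward: returns max(x, 0) with an integer mask attribute */
SEXP C_relu(SEXP X)
{
    R_xlen_t n = XLENGTH(X);
    SEXP out = PROTECT(duplicate(X));
    SEXP mask = PROTECT(allocVector(INTSXP, n));
    double *o = REAL(out);
    int *m = INTEGER(mask);
    for (R_xlen_t i = 0; i < n; i++) {
        if (o[i] > 0) m[i] = 1; else { o[i] = 0.0; m[i] = 0; }
    }
    setAttrib(out, install("mask"), mask);
    UNPROTECT(2);
    return out;
}

/* multiply dy by a 0/1 mask, in place (dy owned by the caller) */
SEXP C_mask_mul(SEXP DY, SEXP MASK)
{
    R_xlen_t n = XLENGTH(DY);
    double *d = REAL(DY);
    int *m = INTEGER(MASK);
    for (R_xlen_t i = 0; i < n; i++) if (!m[i]) d[i] = 0.0;
    return DY;
}

/* im2col for 1D convolution. x is [B, C, D] (column-major, B fastest);
 * returns [B*L, C*K] with X2[b + B*l, c + C*k] = x[b, c, l + k]. */
SEXP C_im2col(SEXP X, SEXP dims_, SEXP K_)
{
    int *dims = INTEGER(dims_);
    int B = dims[0], C = dims[1], D = dims[2], K = asInteger(K_);
    int L = D - K + 1;
    SEXP out = PROTECT(allocMatrix(REALSXP, B * L, C * K));
    double *o = REAL(out), *x = REAL(X);
    for (int k = 0; k < K; k++)
        for (int c = 0; c < C; c++)
            for (int l = 0; l < L; l++)
                memcpy(o + ((size_t)(k * C + c) * L + l) * B,
                       x + ((size_t)(l + k) * C + c) * B, B * sizeof(double));
    UNPROTECT(1);
    return out;
}

/* col2im (transpose of im2col): accumulates dX2 [B*L, C*K] back into
 * dX [B, C, D]. */
SEXP C_col2im(SEXP DX2, SEXP dims_, SEXP K_)
{
    int *dims = INTEGER(dims_);
    int B = dims[0], C = dims[1], D = dims[2], K = asInteger(K_);
    int L = D - K + 1;
    SEXP out = PROTECT(alloc3DArray(REALSXP, B, C, D));
    double *o = REAL(out), *d2 = REAL(DX2);
    memset(o, 0, (size_t)B * C * D * sizeof(double));
    for (int k = 0; k < K; k++)
        for (int c = 0; c < C; c++)
            for (int l = 0; l < L; l++) {
                double *dst = o + ((size_t)(l + k) * C + c) * B;
                double *src = d2 + ((size_t)(k * C + c) * L + l) * B;
                for (int b = 0; b < B; b++) dst[b] += src[b];
            }
    UNPROTECT(1);
    return out;
}

/* transpose [B, C, L] -> matrix [B*L, C] (batch/position rows) */
SEXP C_bcl_to_blc(SEXP X, SEXP dims_)
{
    int *dims = INTEGER(dims_);
    int B = dims[0], C = dims[1], L = dims[2];
    SEXP out = PROTECT(allocMatrix(REALSXP, B * L, C));
    double *o = REAL(out), *x = REAL(X);
    for (int c = 0; c < C; c++)
        for (int l = 0; l < L; l++)
            memcpy(o + ((size_t)c * L + l) * B,
                   x + ((size_t)l * C + c) * B, B * sizeof(double));
    UNPROTECT(1);
    return out;
}

/* inverse of C_bcl_to_blc */
SEXP C_blc_to_bcl(SEXP X2, SEXP dims_)
{
    int *dims = INTEGER(dims_);
    int B = dims[0], C = dims[1], L = dims[2];
    SEXP out = PROTECT(alloc3DArray(REALSXP, B, C, L));
    double *o = REAL(out), *x = REAL(X2);
    for (int c = 0; c < C; c++)
        for (int l = 0; l < L; l++)
            memcpy(o + ((size_t)l * C + c) * B,
                   x + ((size_t)c * L + l) * B, B * sizeof(double));
    UNPROTECT(1);
    return out;
}

/* max pooling (kernel 2) over the last dim of [B, C, L]; returns the
 * pooled array with an integer mask attribute (1 if the first of the pair
 * won). */
SEXP C_maxpool2(SEXP X, SEXP dims_)
{
    int *dims = INTEGER(dims_);
    int B = dims[0], C = dims[1], L = dims[2];
    int Lo = L / 2;
    size_t plane = (size_t)B * C;
    SEXP out = PROTECT(alloc3DArray(REALSXP, B, C, Lo));
    SEXP mask = PROTECT(allocVector(INTSXP, plane * Lo));
    double *o = REAL(out), *x = REAL(X);
    int *m = INTEGER(mask);
    for (int l = 0; l < Lo; l++) {
        double *a = x + plane * (2 * l);
        double *b = x + plane * (2 * l + 1);
        double *y = o + plane * l;
        int *mm = m + plane * l;
        for (size_t i = 0; i < plane; i++) {
            if (a[i] >= b[i]) { y[i] = a[i]; mm[i] = 1; }
            else { y[i] = b[i]; mm[i] = 0; }
        }
    }
    setAttrib(out, install("mask"), mask);
    UNPROTECT(2);
    return out;
}

SEXP C_maxpool2_backward(SEXP DY, SEXP MASK, SEXP dims_)
{
    int *dims = INTEGER(dims_);
    int B = dims[0], C = dims[1], L = dims[2];
    int Lo = L / 2;
    size_t plane = (size_t)B * C;
    SEXP out = PROTECT(alloc3DArray(REALSXP, B, C, L));
    double *o = REAL(out), *dy = REAL(DY);
    int *m = INTEGER(MASK);
    memset(o, 0, (size_t)B * C * L * sizeof(double));
    for (int l = 0; l < Lo; l++) {
        double *a = o + plane * (2 * l);
        double *b = o + plane * (2 * l + 1);
        double *d = dy + plane * l;
        int *mm = m + plane * l;
        for (size_t i = 0; i < plane; i++) {
            if (mm[i]) a[i] = d[i]; else b[i] = d[i];
        }
    }
    UNPROTECT(1);
    return out;
}

/* replay buffer: columns of BUF [feat x capacity] hold flattened
 * observations; write-in-place and batched gather avoid duplicating the
 * (large) buffer on every store */
SEXP C_buf_write(SEXP BUF, SEXP pos_, SEXP X)
{
    R_xlen_t feat = nrows(BUF);
    R_xlen_t pos = (R_xlen_t) asInteger(pos_) - 1;
    memcpy(REAL(BUF) + pos * feat, REAL(X), feat * sizeof(double));
    return R_NilValue;
}

/* gather columns idx (1-based) of BUF [C*D x cap] into [B, C, D] */
SEXP C_buf_gather(SEXP BUF, SEXP idx_, SEXP dims_)
{
    int *dims = INTEGER(dims_);      /* C, D */
    int C = dims[0], D = dims[1];
    int B = LENGTH(idx_);
    int *idx = INTEGER(idx_);
    R_xlen_t feat = (R_xlen_t)C * D;
    SEXP out = PROTECT(alloc3DArray(REALSXP, B, C, D));
    double *o = REAL(out), *buf = REAL(BUF);
    for (int b = 0; b < B; b++) {
        double *src = buf + (R_xlen_t)(idx[b] - 1) * feat;
        for (R_xlen_t i = 0; i < feat; i++)
            o[b + (R_xlen_t)B * i] = src[i];   /* [b, c, z] <- x[c + C*z] */
    }
    UNPROTECT(1);
    return out;
}

static const R_CallMethodDef CallEntries[] = {
    {"C_adam_step",          (DL_FUNC) &C_adam_step,          9},
    {"C_soft_update",        (DL_FUNC) &C_soft_update,        3},
    {"C_add_bias",           (DL_FUNC) &C_add_bias,           2},
    {"C_relu",               (DL_FUNC) &C_relu,               1},
    {"C_mask_mul",           (DL_FUNC) &C_mask_mul,           2},
    {"C_im2col",             (DL_FUNC) &C_im2col,             3},
    {"C_col2im",             (DL_FUNC) &C_col2im,             3},
    {"C_bcl_to_blc",         (DL_FUNC) &C_bcl_to_blc,         2},
    {"C_blc_to_bcl",         (DL_FUNC) &C_blc_to_bcl,         2},
    {"C_maxpool2",           (DL_FUNC) &C_maxpool2,           2},
    {"C_maxpool2_backward",  (DL_FUNC) &C_maxpool2_backward,  3},
    {"C_buf_write",          (DL_FUNC) &C_buf_write,          3},
    {"C_buf_gather",         (DL_FUNC) &C_buf_gather,         3},
    {NULL, NULL, 0}
};

void R_init_octfocus(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, TRUE);
}
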