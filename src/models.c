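/* Right-hand sides of the five homeostat networks, in the deSolve
 * compiled-function convention: one init routine per model copies the
 * parameter vector (fixed order, see R/models.R) into a static array,
 * and one derivs routine fills ydot.  The R-level rhs_*() functions in
 * R/models.R are the reference implementations; tests assert agreement
 * to machine precision.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* ---- motif-2 coherent oscillator -------------------------------------
 * params: k2 k3 k4 k5 k6 k7 k8 k9 k10 k11 k12 k13 k14 k15 k16 k17 kg kg3
 * state:  A e E I1 I2
 */
static double pm2c[18];
void hm_init_m2_coherent(void (*odeparms)(int *, double *))
{
    int n = 18;
    odeparms(&n, pm2c);
}
void hm_d_m2_coherent(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    const double *k = pm2c;
    double A = y[0], e = y[1], E = y[2], I1 = y[3], I2 = y[4];
    /* k[0]=k2 k[1]=k3 k[2]=k4 k[3]=k5 k[4]=k6 k[5]=k7 k[6]=k8 k[7]=k9
       k[8]=k10 k[9]=k11 k[10]=k12 k[11]=k13 k[12]=k14 k[13]=k15
       k[14]=k16 k[15]=k17 k[16]=kg k[17]=kg3 */
    ydot[0] = k[17] * I2 + k[1] * k[3] / (k[3] + E)
            - k[16] * A * I1 / (k[15] + A)
            - k[0] * A / (k[6] + A)
            - k[8] * A / (k[6] + A);
    ydot[1] = k[2] * A - k[7] * e;
    ydot[2] = k[7] * e - k[4] * E / (k[5] + E);
    ydot[3] = k[9] * E - k[10] * I1 / (k[11] + I1);
    ydot[4] = k[12] - (k[13] * I2 / (k[14] + I2)) * E;
}

/* ---- motif-8 coherent oscillator -------------------------------------
 * params: k1 k3 k4 k5 k6 k7 k8 k9 k10 k11 k12 k13 k14 k15 k16 k17 k18 kg1 kg2
 * state:  A e E I1 I2
 */
static double pm8c[19];
void hm_init_m8_coherent(void (*odeparms)(int *, double *))
{
    int n = 19;
    odeparms(&n, pm8c);
}
void hm_d_m8_coherent(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    const double *k = pm8c;
    double A = y[0], e = y[1], E = y[2], I1 = y[3], I2 = y[4];
    /* k[0]=k1 k[1]=k3 k[2]=k4 k[3]=k5 k[4]=k6 k[5]=k7 k[6]=k8 k[7]=k9
       k[8]=k10 k[9]=k11 k[10]=k12 k[11]=k13 k[12]=k14 k[13]=k15
       k[14]=k16 k[15]=k17 k[16]=k18 k[17]=kg1 k[18]=kg2 */
    ydot[0] = k[0] + k[1]
            - (k[18] * A / (k[16] + A)) * I2
            + k[17] * I1
            - (k[2] * A / (k[3] + A)) * (k[7] / (k[7] + E));
    ydot[1] = k[4] * k[8] / (k[8] + A) - k[9] * e;
    ydot[2] = k[9] * e - k[5] * E / (k[6] + E);
    ydot[3] = k[10] * E - k[11] * I1 / (k[12] + I1);
    ydot[4] = k[13] - (k[14] * I2 / (k[15] + I2)) * E;
}

/* ---- motif-2 first-order (non-oscillatory) ---------------------------
 * params: k1 k2 k3 k4 k5 k6 k7 k8 k9 k10 k11 k12 k13 k14 k15 k16 k17 kg kg3
 * state:  A e E I1 I2
 * A-removals are first order in A; e/E/I1/I2 equations as in the
 * coherent m2 scheme.
 */
static double pm2f[19];
void hm_init_m2_firstorder(void (*odeparms)(int *, double *))
{
    int n = 19;
    odeparms(&n, pm2f);
}
void hm_d_m2_firstorder(int *neq, double *t, double *y, double *ydot,
                        double *yout, int *ip)
{
    const double *k = pm2f;
    double A = y[0], e = y[1], E = y[2], I1 = y[3], I2 = y[4];
    /* k[0]=k1 k[1]=k2 k[2]=k3 k[3]=k4 k[4]=k5 k[5]=k6 k[6]=k7 k[7]=k8
       k[8]=k9 k[9]=k10 k[10]=k11 k[11]=k12 k[12]=k13 k[13]=k14
       k[14]=k15 k[15]=k16 k[16]=k17 k[17]=kg k[18]=kg3 */
    ydot[0] = k[0] + k[18] * I2 + k[2] * k[4] / (k[4] + E)
            - k[17] * A * I1 - k[1] * A - k[9] * A;
    ydot[1] = k[3] * A - k[8] * e;
    ydot[2] = k[8] * e - k[5] * E / (k[6] + E);
    ydot[3] = k[10] * E - k[11] * I1 / (k[12] + I1);
    ydot[4] = k[13] - (k[14] * I2 / (k[15] + I2)) * E;
}

/* ---- dual inflow-controller scheme -----------------------------------
 * params: k2 k3 k4 k5 k6 k7 k9 k10 k11 k12 k13 k14 k15 k16 k17 k18 k19 k20 kg kg3
 * state:  A a E1 E2 I1 I2
 */
static double pde[20];
void hm_init_dual_e(void (*odeparms)(int *, double *))
{
    int n = 20;
    odeparms(&n, pde);
}
void hm_d_dual_e(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    const double *k = pde;
    double A = y[0], a = y[1], E1 = y[2], E2 = y[3], I1 = y[4], I2 = y[5];
    /* k[0]=k2 k[1]=k3 k[2]=k4 k[3]=k5 k[4]=k6 k[5]=k7 k[6]=k9 k[7]=k10
       k[8]=k11 k[9]=k12 k[10]=k13 k[11]=k14 k[12]=k15 k[13]=k16
       k[14]=k17 k[15]=k18 k[16]=k19 k[17]=k20 k[18]=kg k[19]=kg3 */
    ydot[0] = k[18] * I2 - k[19] * A * I1 - k[0] * A - k[7] * A
            + k[6] * a + k[8] * E2;
    ydot[1] = k[1] * k[3] / (k[3] + E1) - k[6] * a;
    ydot[2] = k[2] * A - k[4] * E1 / (k[5] + E1);
    ydot[3] = k[9] - A * (k[10] * E2 / (k[11] + E2));
    ydot[4] = k[12] - (k[13] * I1 / (k[14] + I1)) * E2;
    ydot[5] = k[15] * E2 - k[16] * I2 / (k[17] + I2);
}

/* ---- motif-2 incoherent-feedback oscillator --------------------------
 * params: k2 k3 k4 k5 k6 k7 k9 k10 k11 k12 k13 k14 k15 k16 kg kg3
 * state:  A a E I1 I2
 */
static double pinc[16];
void hm_init_m2_incoherent(void (*odeparms)(int *, double *))
{
    int n = 16;
    odeparms(&n, pinc);
}
void hm_d_m2_incoherent(int *neq, double *t, double *y, double *ydot,
                        double *yout, int *ip)
{
    const double *k = pinc;
    double A = y[0], a = y[1], E = y[2], I1 = y[3], I2 = y[4];
    /* k[0]=k2 k[1]=k3 k[2]=k4 k[3]=k5 k[4]=k6 k[5]=k7 k[6]=k9 k[7]=k10
       k[8]=k11 k[9]=k12 k[10]=k13 k[11]=k14 k[12]=k15 k[13]=k16
       k[14]=kg k[15]=kg3 */
    ydot[0] = k[6] * a - k[0] * A - k[7] * A;
    ydot[1] = (k[15] * I2 + k[1] / (k[3] + E)) * k[3]
            - k[14] * a * I1 - k[6] * a;
    ydot[2] = k[2] * A - k[4] * E / (k[5] + E);
    ydot[3] = k[8] * E - k[9] * I1 / (k[10] + I1);
    ydot[4] = k[11] - (k[12] * I2 / (k[13] + I2)) * E;
}

/* ---- registration ---------------------------------------------------- */
static const R_CMethodDef cMethods[] = {
    {"hm_init_m2_coherent",   (DL_FUNC) &hm_init_m2_coherent,   1},
    {"hm_d_m2_coherent",      (DL_FUNC) &hm_d_m2_coherent,      6},
    {"hm_init_m8_coherent",   (DL_FUNC) &hm_init_m8_coherent,   1},
    {"hm_d_m8_coherent",      (DL_FUNC) &hm_d_m8_coherent,      6},
    {"hm_init_m2_firstorder", (DL_FUNC) &hm_init_m2_firstorder, 1},
    {"hm_d_m2_firstorder",    (DL_FUNC) &hm_d_m2_firstorder,    6},
    {"hm_init_dual_e",        (DL_FUNC) &hm_init_dual_e,        1},
    {"hm_d_dual_e",           (DL_FUNC) &hm_d_dual_e,           6},
    {"hm_init_m2_incoherent", (DL_FUNC) &hm_init_m2_incoherent, 1},
    {"hm_d_m2_incoherent",    (DL_FUNC) &hm_d_m2_incoherent,    6},
    {NULL, NULL, 0}
};

void R_init_homeostat(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
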