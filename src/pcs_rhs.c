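/* Right-hand side of the 18-state plant circadian system (PCS) ODE model:
 * compact clock (CL, P97, P51, EL, PIF), PIF-driven hypocotyl growth,
 * phyA/phyB/cry1 photoreceptors, and competitive photoreceptor-COP1 binding.
 *
 * Compiled-code interface for deSolve: parameters are passed once per light
 * segment (light intensities are piecewise constant, so the segment's I_red
 * and I_blue ride along at the tail of the parameter vector and the light
 * indicator functions are constant within a solver call).
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define N_PARMS 77

/* canonical parameter order; must match .pcs_par_names in R/parameters.R */
#define P_v1     p[0]
#define P_v2     p[1]
#define P_v3     p[2]
#define P_v4     p[3]
#define P_v5     p[4]
#define P_K1     p[5]
#define P_K2     p[6]
#define P_K3     p[7]
#define P_K4     p[8]
#define P_K5     p[9]
#define P_K6     p[10]
#define P_K7     p[11]
#define P_K8     p[12]
#define P_K9     p[13]
#define P_K10    p[14]
#define P_K11    p[15]
#define P_K12    p[16]
#define P_k1L    p[17]
#define P_k1D    p[18]
#define P_k2     p[19]
#define P_k3     p[20]
#define P_k4     p[21]
#define P_k5     p[22]
#define P_p1     p[23]
#define P_p1L    p[24]
#define P_p2     p[25]
#define P_p3     p[26]
#define P_p4     p[27]
#define P_p5     p[28]
#define P_d1     p[29]
#define P_d2D    p[30]
#define P_d2L    p[31]
#define P_d3D    p[32]
#define P_d3L    p[33]
#define P_d4D    p[34]
#define P_d4L    p[35]
#define P_d5D    p[36]
#define P_d5L    p[37]
#define P_g1     p[38]
#define P_g2     p[39]
#define P_Ap3    p[40]
#define P_Am7    p[41]
#define P_Ak7    p[42]
#define P_q2     p[43]
#define P_Bp4    p[44]
#define P_Bm8    p[45]
#define P_Bk8    p[46]
#define P_Cp5    p[47]
#define P_Cm9    p[48]
#define P_Ck9    p[49]
#define P_q1a    p[50]
#define P_q3a    p[51]
#define P_q4a    p[52]
#define P_q1b    p[53]
#define P_q3b    p[54]
#define P_q4b    p[55]
#define P_eta1   p[56]
#define P_eta2   p[57]
#define P_kmpac  p[58]
#define P_kmpbc  p[59]
#define P_kmpcc  p[60]
#define P_kd     p[61]
#define P_de1    p[62]
#define P_de2    p[63]
#define P_de3    p[64]
#define P_de4    p[65]
#define P_de5    p[66]
#define P_Ctot   p[67]
#define P_cox    p[68]
/* runtime extras appended by the R wrapper */
#define P_ox1    p[69]
#define P_ox2    p[70]
#define P_ox3    p[71]
#define P_ox4    p[72]
#define P_ox5    p[73]
#define P_Ired   p[74]
#define P_Iblue  p[75]
#define P_cdecay p[76]  /* 1: complex decay terms use the complex concentration */

static double p[N_PARMS];

void pcs_init(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, p);
}

/* state indices (0-based) */
#define S_CLm   y[0]
#define S_CLp   y[1]
#define S_P97m  y[2]
#define S_P97p  y[3]
#define S_P51m  y[4]
#define S_P51p  y[5]
#define S_ELm   y[6]
#define S_ELp   y[7]
#define S_PIFm  y[8]
#define S_PIFp  y[9]
#define S_HYP   y[10]
#define S_PhyA  y[11]
#define S_PhyB  y[12]
#define S_Cry1  y[13]
#define S_COP1  y[14]
#define S_CPA   y[15]
#define S_CPB   y[16]
#define S_CC1   y[17]

static double sq(double x) { return x * x; }

void pcs_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    /* light indicators: any positive intensity flips the flag */
    const double thB = (P_Ired  > 0.0) ? 1.0 : 0.0;
    const double thC = (P_Iblue > 0.0) ? 1.0 : 0.0;
    const double thA = (thB > 0.0 || thC > 0.0) ? 1.0 : 0.0;

    /* total photoreceptor pools (free + COP1-bound) */
    const double TA = S_PhyA + S_CPA;
    const double TB = S_PhyB + S_CPB;
    const double TC = S_Cry1 + S_CC1;

    const double logR = log(P_eta1 * P_Ired  + 1.0);
    const double logB = log(P_eta2 * P_Iblue + 1.0);

    const double La = P_q1a * TA * thA + P_q3a * TB * logR * thB +
                      P_q4a * TC * logB * thC;
    const double Lb = P_q1b * TA * thA + P_q3b * TB * logR * thB +
                      P_q4b * TC * logB * thC;

    /* core clock */
    ydot[0] = (P_v1 + La) / (1.0 + sq(S_P97p / P_K1) + sq(S_P51p / P_K2)) +
              P_ox1 - (P_k1L * thA + P_k1D * (1.0 - thA)) * S_CLm;
    ydot[1] = (P_p1 + P_p1L * thA) * S_CLm - P_d1 * S_CLp;
    ydot[2] = (P_v2 + Lb) /
              (1.0 + sq(S_CLp / P_K3) + sq(S_P51p / P_K4) + sq(S_ELp / P_K5)) +
              P_ox2 - P_k2 * S_P97m;
    ydot[3] = P_p2 * S_P97m - (P_d2D * (1.0 - thA) + P_d2L * thA) * S_P97p;
    ydot[4] = P_v3 / (1.0 + sq(S_CLp / P_K6) + sq(S_P51p / P_K7)) +
              P_ox3 - P_k3 * S_P51m;
    ydot[5] = P_p3 * S_P51m - (P_d3D * (1.0 - thA) + P_d3L * thA) * S_P51p;
    /* evening-complex transcription only in light; an overexpression
     * constant on EL shares the light gate (a dark-grown EL transgene
     * product is unstable, and constant-dark overexpression leaves the
     * rhythm at its wild-type dark period) */
    ydot[6] = thA * (P_v4 /
              (1.0 + sq(S_CLp / P_K8) + sq(S_P51p / P_K9) + sq(S_ELp / P_K10)) +
              P_ox4) - P_k4 * S_ELm;
    /* EL protein: COP1-dependent degradation; free COP1 and each complex
     * contribute with their own activity, normalised by total COP1 */
    ydot[7] = P_p4 * S_ELm - P_de1 * S_ELp -
              ((P_de2 * S_COP1 + P_de3 * S_CPA) / P_Ctot) * S_ELp -
              ((P_de4 * S_CPB + P_de5 * S_CC1) / P_Ctot) * S_ELp;
    /* growth arm */
    ydot[8] = P_v5 / (1.0 + sq(S_ELp / P_K11)) + P_ox5 - P_k5 * S_PIFm;
    ydot[9] = P_p5 * S_PIFm - (P_d5D * (1.0 - thA) + P_d5L * thA) * S_PIFp;
    ydot[10] = P_g1 + P_g2 * sq(S_PIFp) / (sq(P_K12) + sq(S_PIFp));

    /* photoreceptors with COP1 exchange */
    ydot[11] = (1.0 - thA) * P_Ap3 - P_Am7 * S_PhyA / (P_Ak7 + S_PhyA) -
               P_q2 * thA * S_PhyA -
               P_kmpac * thA * S_PhyA * S_COP1 + P_kd * S_CPA;
    ydot[12] = P_Bp4 - P_Bm8 * S_PhyB / (P_Bk8 + S_PhyB) -
               P_kmpbc * thB * S_PhyB * S_COP1 + P_kd * S_CPB;
    ydot[13] = P_Cp5 - P_Cm9 * S_Cry1 / (P_Ck9 + S_Cry1) -
               P_kmpcc * thC * S_Cry1 * S_COP1 + P_kd * S_CC1;

    /* COP1 and complexes; the saturable decay of the phyB/cry1 complexes is
     * written against the free photoreceptor in the source formulation, with
     * a switch to the complex-concentration reading */
    const double decB = (P_cdecay > 0.5) ? S_CPB : S_PhyB;
    const double decC = (P_cdecay > 0.5) ? S_CC1 : S_Cry1;

    ydot[14] = -P_kmpac * thA * S_PhyA * S_COP1 + P_kd * S_CPA +
               P_kd * S_CPB - P_kmpbc * thB * S_PhyB * S_COP1 -
               P_kmpcc * thC * S_Cry1 * S_COP1 + P_kd * S_CC1 +
               P_Am7 * S_CPA / (P_Ak7 + S_CPA) + P_q2 * thA * S_CPA +
               P_Bm8 * S_CPB / (P_Bk8 + S_CPB) +
               P_Cm9 * S_CC1 / (P_Ck9 + S_CC1);
    ydot[15] = P_kmpac * thA * S_PhyA * S_COP1 - P_kd * S_CPA -
               P_Am7 * S_CPA / (P_Ak7 + S_CPA) - P_q2 * thA * S_CPA;
    ydot[16] = P_kmpbc * thB * S_PhyB * S_COP1 - P_kd * S_CPB -
               P_Bm8 * decB / (P_Bk8 + decB);
    ydot[17] = P_kmpcc * thC * S_Cry1 * S_COP1 - P_kd * S_CC1 -
               P_Cm9 * decC / (P_Ck9 + decC);

    if (ip[0] >= 5) {
        yout[0] = TA;
        yout[1] = TB;
        yout[2] = TC;
        yout[3] = La;
        yout[4] = Lb;
    }
}

/* one-shot RHS evaluation from R (used by clock_rhs()) */
SEXP pcs_rhs_call(SEXP y_, SEXP parms_)
{
    if (LENGTH(parms_) != N_PARMS)
        error("expected %d parameters, got %d", N_PARMS, LENGTH(parms_));
    if (LENGTH(y_) != 18)
        error("expected 18 states, got %d", LENGTH(y_));
    for (int i = 0; i < N_PARMS; i++) p[i] = REAL(parms_)[i];
    SEXP out = PROTECT(allocVector(REALSXP, 18));
    double t = 0.0, yout[5];
    int neq = 18, ip[1] = {0};
    pcs_derivs(&neq, &t, REAL(y_), REAL(out), yout, ip);
    UNPROTECT(1);
    return out;
}

static const R_CallMethodDef callMethods[] = {
    {"pcs_rhs_call", (DL_FUNC) &pcs_rhs_call, 2},
    {NULL, NULL, 0}
};

static const R_CMethodDef cMethods[] = {
    {"pcs_derivs", (DL_FUNC) &pcs_derivs, 6},
    {"pcs_init",   (DL_FUNC) &pcs_init,   0},
    {NULL, NULL, 0}
};

void R_init_phytoclock(DllInfo *info)
{
    R_registerRoutines(info, cMethods, callMethods, NULL, NULL);
    /* deSolve resolves "pcs_derivs"/"pcs_init" by name at run time */
    R_useDynamicSymbols(info, TRUE);
}
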