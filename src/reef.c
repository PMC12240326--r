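/* Compiled right-hand side of the reef model for deSolve.
 *
 * State order: C, T, M, G, B, R.
 * Parameter order must match param_vector() on the R side:
 *   i_C, i_T, i_M, b_C, b_T, b_M, d_C, gamma, g_T, g_M,
 *   eta_T, eta_M, alpha_T, alpha_M, r, sigma, f
 */
#include <R.h>

static double parms[17];

#define iC      parms[0]
#define iT      parms[1]
#define iM      parms[2]
#define bC      parms[3]
#define bT      parms[4]
#define bM      parms[5]
#define dC_     parms[6]
#define gam     parms[7]
#define gT      parms[8]
#define gM      parms[9]
#define etaT    parms[10]
#define etaM    parms[11]
#define alphaT  parms[12]
#define alphaM  parms[13]
#define r_      parms[14]
#define sigma_  parms[15]
#define f_      parms[16]

void reef_initmod(void (* odeparms)(int *, double *))
{
    int n = 17;
    odeparms(&n, parms);
}

void reef_rhs(int *neq, double *t, double *y, double *ydot,
              double *yout, int *ip)
{
    /* clip transient float negatives so Holling terms and the space
       constraint stay well-behaved near invariant manifolds */
    double C = y[0] > 0 ? y[0] : 0;
    double T = y[1] > 0 ? y[1] : 0;
    double M = y[2] > 0 ? y[2] : 0;
    double G = y[3] > 0 ? y[3] : 0;
    double B = y[4] > 0 ? y[4] : 0;
    double R = y[5] > 0 ? y[5] : 0;

    double S    = 1.0 - C - T - M;
    double denT = gT * etaT * T + 1.0;
    double denM = gM * etaM * M + 1.0;
    double denR = gT * etaT * T + gM * etaM * M + 1.0;
    double K    = (1.0 - sigma_) + sigma_ * C;
    double H    = G + B + R;
    double crowd = (H == 0.0 && K == 0.0) ? 0.0 : 1.0 - H / K;

    ydot[0] = (iC + bC * C) * S * (1.0 - (alphaT * T + alphaM * M)) - dC_ * C;
    ydot[1] = (iT + bT * T) * S - gam * T
              - gT * T * G / denT - gT * T * R / denR;
    ydot[2] = (iM + bM * M) * S + gam * T
              - gM * M * B / denM - gM * M * R / denR;
    ydot[3] = r_ * G * crowd - f_ * G;
    ydot[4] = r_ * B * crowd - f_ * B;
    ydot[5] = r_ * R * crowd - f_ * R;
}
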