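/* Compiled right-hand side of the combined batch-culture model, used through
   deSolve's compiled-model interface. Parameter layout must match
   .compiled_parms() on the R side:
     0..22  Vg Kg Ka Ve Ke Kae kd eps2 k0 a0 VR CR CA k3 gamma KR KL
            eps0 eps1 eps3 eps4 (23 values, canonical flat order minus VL/kdL
            which are entries 16/18 there; here VL is dropped and kdL moved)
   Exact layout (26 slots):
     [0] Vg  [1] Kg  [2] Ka  [3] Ve  [4] Ke  [5] Kae  [6] kd  [7] eps2
     [8] k0  [9] a0  [10] VR [11] CR [12] CA [13] k3  [14] gamma [15] KR
     [16] KL [17] eps0 [18] eps1 [19] eps3 [20] eps4
     [21] activation exponent (1 or 2)
     [22] include growth cost (0/1)
     [23] adenylate pool size (<= 0 means none)
     [24] kdL
     [25] reserved
   State: y = (S, N, a, A, R, L). Small negative excursions from the solver
   are clamped to zero for rate evaluation only; the integrator state itself
   is never modified. */

#include <R.h>

static double parms[26];

#define P_Vg    parms[0]
#define P_Kg    parms[1]
#define P_Ka    parms[2]
#define P_Ve    parms[3]
#define P_Ke    parms[4]
#define P_Kae   parms[5]
#define P_kd    parms[6]
#define P_eps2  parms[7]
#define P_k0    parms[8]
#define P_a0    parms[9]
#define P_VR    parms[10]
#define P_CR    parms[11]
#define P_CA    parms[12]
#define P_k3    parms[13]
#define P_gam   parms[14]
#define P_KR    parms[15]
#define P_KL    parms[16]
#define P_eps0  parms[17]
#define P_eps1  parms[18]
#define P_eps3  parms[19]
#define P_eps4  parms[20]
#define P_nact  parms[21]
#define P_gcost parms[22]
#define P_pool  parms[23]
#define P_kdL   parms[24]

void qslum_initmod(void (*odeparms)(int *, double *))
{
    int n = 26;
    odeparms(&n, parms);
}

void qslum_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double S = y[0] > 0 ? y[0] : 0;
    double N = y[1] > 0 ? y[1] : 0;
    double a = y[2] > 0 ? y[2] : 0;
    double A = y[3] > 0 ? y[3] : 0;
    double R = y[4] > 0 ? y[4] : 0;
    double L = y[5] > 0 ? y[5] : 0;

    double an   = (P_nact > 1.5) ? a * a : a;
    double pf   = 1.0;
    if (P_pool > 0) {
        pf = 1.0 - a / P_pool;
        if (pf < 0) pf = 0;
    }
    double fe   = P_Ve * S / (P_Ke + S) * an / (P_Kae + an) * pf;
    double fg   = P_Vg * S / (P_Kg + S) * a / (P_Ka + a);
    double cost = (P_gcost > 0.5) ? P_k0 * fg : 0.0;
    double RA   = R * A;
    double D    = RA * RA / P_gam;
    double prom = D / (P_KR + D);

    ydot[0] = -P_eps0 * N * (fe + P_k0 * fg);
    ydot[1] = fg * N;
    ydot[2] = (fe - cost - P_kd * a / (P_eps2 + a)) / P_eps1;
    ydot[3] = P_CA * N;
    ydot[4] = (P_CR + P_VR * (a / (P_a0 + a)) * prom - P_k3 * R) / P_eps3;
    ydot[5] = ((a / (P_KL + a)) * prom - P_kdL * L) / P_eps4;
}
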