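/* Seven-variable ATM / p53 / Mdm2 / Wip1 network, compiled right-hand side
 * for deSolve.  Parameter vector layout (must match R side, see params.R):
 *   [0..21]  the 22 kinetic rate constants in canonical order
 *   [22]     Hill exponent n for p53-dependent transcription (fixed)
 *   [23]     t_ir    irradiation time (h)
 *   [24]     decay   damage repair rate (1/h); 0 = persistent damage
 *   [25]     e_on    master damage switch (0/1)
 * State vector: S, Pi, Pa, Zm, M, Zw, W.
 */
#include <R.h>
#include <math.h>

#define NPARMS 26
static double parms[NPARMS];

#define k_beta_s    parms[0]
#define k_alpha_s   parms[1]
#define k_alpha_ws  parms[2]
#define k_beta_p    parms[3]
#define k_alpha_pi  parms[4]
#define k_alpha_mpi parms[5]
#define k_beta_sp   parms[6]
#define k_T_s       parms[7]
#define k_alpha_wpa parms[8]
#define k_alpha_mpa parms[9]
#define k_beta_mt   parms[10]
#define k_beta_pamt parms[11]
#define k_T_pa      parms[12]
#define k_alpha_mt  parms[13]
#define k_beta_mtm  parms[14]
#define k_alpha_m   parms[15]
#define k_alpha_sm  parms[16]
#define k_beta_wt   parms[17]
#define k_beta_pawt parms[18]
#define k_alpha_wt  parms[19]
#define k_beta_wtw  parms[20]
#define k_alpha_w   parms[21]
#define k_hill_n    parms[22]
#define k_t_ir      parms[23]
#define k_decay     parms[24]
#define k_e_on      parms[25]

void p53_initmod(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

void p53_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double S = y[0], Pi = y[1], Pa = y[2], Zm = y[3],
           M = y[4], Zw = y[5], W = y[6];
    double E = 0.0;

    if (k_e_on > 0.5 && *t >= k_t_ir)
        E = (k_decay > 0.0) ? exp(-k_decay * (*t - k_t_ir)) : 1.0;

    /* saturable ATM-mediated p53 activation and Hill-type target-gene
       induction; guard against transiently negative solver states */
    double Sp = (S > 0.0) ? S : 0.0;
    double Pap = (Pa > 0.0) ? Pa : 0.0;
    double act = k_beta_sp * Sp / (k_T_s + Sp);
    double hn = pow(Pap, k_hill_n);
    double hill = hn / (pow(k_T_pa, k_hill_n) + hn);

    ydot[0] = k_beta_s * E - k_alpha_s * S - k_alpha_ws * W * S;
    ydot[1] = k_beta_p - k_alpha_pi * Pi - k_alpha_mpi * M * Pi
              - act * Pi + k_alpha_wpa * W * Pa;
    ydot[2] = act * Pi - k_alpha_wpa * W * Pa - k_alpha_mpa * M * Pa;
    ydot[3] = k_beta_mt + k_beta_pamt * hill - k_alpha_mt * Zm;
    ydot[4] = k_beta_mtm * Zm - k_alpha_m * M - k_alpha_sm * S * M;
    ydot[5] = k_beta_wt + k_beta_pawt * hill - k_alpha_wt * Zw;
    ydot[6] = k_beta_wtw * Zw - k_alpha_w * W;

    if (ip[0] >= 1)
        yout[0] = Pi + Pa; /* total p53 */
}
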