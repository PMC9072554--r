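/* Compiled right-hand side of the Nrf2 pathway ODE model, for use with
 * deSolve (dllname = "nrf2dyn"). The reaction structure mirrors the
 * network built by build_model(); equivalence of the two evaluation paths
 * is enforced by the test suite.
 *
 * Parameter vector layout (see .c_parms() on the R side):
 *  0 p_Nrf2      1 p_Keap1     2 kt_Keap1    3 p_p62      4 kt_p62
 *  5 kt_Srxn1    6 ka_KN       7 kd_KN       8 kdeg_Nrf2c 9 ka_Kp62
 * 10 k_auto     11 k_clear_auto 12 k_in      13 k_out
 * 14 b_mKEAP1   15 V_mKEAP1   16 K_mKEAP1   17 h_mKEAP1
 * 18 b_mNFE2L2
 * 19 b_mSQSTM1  20 V_mSQSTM1  21 K_mSQSTM1  22 h_mSQSTM1
 * 23 b_mSRXN1   24 V_mSRXN1_eff 25 K_mSRXN1 26 h_mSRXN1
 * 27 b_GSH      28 V_GSH      29 K_GSH      30 h_GSH
 * 31 k_conj
 * 32 d_Nrf2     33 d_Keap1    34 d_p62      35 d_cplx     36 d_nNrf2
 * 37 d_mKEAP1   38 d_mNFE2L2  39 d_mSQSTM1  40 d_mSRXN1
 * 41 d_Srxn1_eff 42 d_GSH
 * 43 k_mod_free_eff 44 k_mod_cplx_eff 45 k_clear_stress_eff
 * 46 variant (0 = hinge-latch, 1 = dissociation)
 * 47 dose      48 onset      49 center_offset 50 width    51 bg
 *
 * State ordering as in species_names():
 *  0 Keap1  1 Nrf2  2 p62  3 K1N2_latch  4 K1N2_mod  5 K1p62
 *  6 Keap1_auto  7 nNrf2  8 mKEAP1  9 mNFE2L2  10 mSQSTM1  11 mSRXN1
 * 12 Srxn1  13 GSH  14 Stress
 */

#include <math.h>

#define N_PARMS 52

static double parms[N_PARMS];

void nrf2_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

static double hill(double x, double V, double K, double h)
{
    double xh = pow(x, h);
    return V * xh / (pow(K, h) + xh);
}

void nrf2_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    const double *p = parms;
    double x[15];
    int i;
    for (i = 0; i < 15; i++) x[i] = y[i] > 0 ? y[i] : 0.0;

    double Keap1 = x[0], Nrf2 = x[1], p62 = x[2], latch = x[3],
           mod = x[4], Kp62 = x[5], autoK = x[6], nN = x[7],
           mK = x[8], mN = x[9], mS = x[10], mX = x[11],
           Srx = x[12], GSH = x[13], S = x[14];

    /* treatment input: Gauss bolus + vehicle background, on after onset */
    double u = 0.0;
    if (*t >= p[48]) {
        double dt = *t - p[48] - p[49];
        u = p[47] * exp(-dt * dt / (2.0 * p[50] * p[50])) + p[51];
    }

    double v_bind  = p[6] * Keap1 * Nrf2;
    double v_unb   = p[7] * latch;
    double v_deg   = p[8] * latch;          /* proteasomal Nrf2 degradation */
    double v_bp62  = p[9] * Keap1 * p62;
    double v_auto  = p[10] * Kp62;
    double v_in    = p[12] * Nrf2;
    double v_out   = p[13] * nN;
    double v_modF  = p[43] * S * Keap1;     /* stress on free Keap1 */
    double v_modC  = p[44] * S * latch;     /* stress on the complex */
    double v_conj  = p[31] * GSH * S;

    double tx_mK = p[14] + hill(nN, p[15], p[16], p[17]);
    double tx_mS = p[19] + hill(nN, p[20], p[21], p[22]);
    double tx_mX = p[23] + hill(nN, p[24], p[25], p[26]);
    double tx_G  = p[27] + hill(nN, p[28], p[29], p[30]);

    int diss = p[46] > 0.5;

    ydot[0] = p[1] + p[2] * mK + v_unb + v_deg
              - v_bind - v_bp62 - v_modF - p[33] * Keap1;
    ydot[1] = p[0] + v_unb + v_out - v_bind - v_in - p[32] * Nrf2
              + (diss ? v_modC : 0.0);
    ydot[2] = p[3] + p[4] * mS - v_bp62 - p[34] * p62;
    ydot[3] = v_bind - v_unb - v_deg - v_modC - p[35] * latch;
    ydot[4] = (diss ? 0.0 : v_modC) - p[35] * mod;
    ydot[5] = v_bp62 - v_auto - p[35] * Kp62;
    ydot[6] = v_auto - p[11] * autoK;
    ydot[7] = v_in - v_out - p[36] * nN;
    ydot[8] = tx_mK - p[37] * mK;
    ydot[9] = p[18] - p[38] * mN;
    ydot[10] = tx_mS - p[39] * mS;
    ydot[11] = tx_mX - p[40] * mX;
    ydot[12] = p[5] * mX - p[41] * Srx;
    ydot[13] = tx_G - v_conj - p[42] * GSH;
    ydot[14] = u - p[45] * S - v_conj - v_modF - v_modC;
}
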