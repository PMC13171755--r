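/* 20-state ODE right-hand side for the murine B cell / ASC response model,
 * compiled for use with deSolve (lsoda).
 *
 * Parameter vector layout (must match .parms_order in R/model.R):
 *  0 ksyn_imm  1 kmat_1  2 kmat_2  3 kmat_3
 *  4..17 k1..k14
 * 18 kdeg_spl 19 kdeg_ln 20 ksin_igg 21 kdeg_igg
 * 22 Vmax 23 Khalf 24 precursor_frequency
 * 25 amplitude 26 rise 27 decay 28 onset 29 ktr
 *
 * State layout (must match asc_state_names()):
 *  0 ImmBone 1 T1Bone 2 T1Blood 3 T1Spleen 4 NaiveSpleen 5 NaiveBlood
 *  6 NaiveLN 7 Antigen0 8..12 Antigen1..Antigen5 13 Antigen
 * 14 ASCSpleen 15 ASCLN 16 ASCBlood 17 ASCBone 18 ASCPeripheral 19 IgGBlood
 */

#include <R.h>
#include <math.h>

static double parms[30];

void asc_initmod(void (*odeparms)(int *, double *))
{
    int n = 30;
    odeparms(&n, parms);
}

void asc_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const double ksyn_imm = parms[0], kmat_1 = parms[1], kmat_2 = parms[2],
                 kmat_3 = parms[3];
    const double k1 = parms[4], k2 = parms[5], k3 = parms[6], k4 = parms[7],
                 k5 = parms[8], k6 = parms[9], k7 = parms[10], k8 = parms[11],
                 k9 = parms[12], k10 = parms[13], k11 = parms[14],
                 k12 = parms[15], k13 = parms[16], k14 = parms[17];
    const double kdeg_spl = parms[18], kdeg_ln = parms[19],
                 ksin_igg = parms[20], kdeg_igg = parms[21];
    const double Vmax = parms[22], Khalf = parms[23], pf = parms[24];
    const double amp = parms[25], rise = parms[26], decay = parms[27],
                 onset = parms[28], ktr = parms[29];

    /* homeostatic lineage and trafficking */
    ydot[0] = ksyn_imm - kmat_1 * y[0];
    ydot[1] = kmat_1 * y[0] - k1 * y[1];
    ydot[2] = k1 * y[1] + k2 * y[3] - k3 * y[2];
    ydot[3] = k3 * y[2] - (k2 + kmat_2) * y[3];
    ydot[4] = kmat_2 * y[3] + k5 * y[5] - (k4 + kdeg_spl) * y[4];
    ydot[5] = k4 * y[4] + k7 * y[6] - (k5 + k6) * y[5];
    ydot[6] = k6 * y[5] - (k7 + kdeg_ln) * y[6];

    /* antigen exposure (first-order absorption form of the Bateman pulse)
     * and the six-stage transit chain */
    double src = 0.0;
    double tt = *t - onset;
    if (tt >= 0.0)
        src = amp * (rise - decay) * exp(-rise * tt);
    ydot[7] = src - decay * y[7];
    ydot[8] = ktr * (y[7] - y[8]);
    ydot[9] = ktr * (y[8] - y[9]);
    ydot[10] = ktr * (y[9] - y[10]);
    ydot[11] = ktr * (y[10] - y[11]);
    ydot[12] = ktr * (y[11] - y[12]);
    ydot[13] = ktr * (y[12] - y[13]);

    /* ASC generation, trafficking, saturable bone-marrow niche influx.
     * ASCBlood is clipped at 0 in the saturable term only. */
    double gen_spl = kmat_3 * y[4] * pf * y[13];
    double gen_ln = kmat_3 * y[6] * pf * y[13];
    double ab = y[16] > 0.0 ? y[16] : 0.0;
    double bone_in = Vmax * ab / (Khalf + ab);

    ydot[14] = gen_spl + k9 * y[16] - k8 * y[14];
    ydot[15] = gen_ln + k10 * y[16] - k11 * y[15];
    ydot[16] = k8 * y[14] + k11 * y[15] + k12 * y[17] + k14 * y[18]
               - (k9 + k10 + k13) * y[16] - bone_in;
    ydot[17] = bone_in - k12 * y[17];
    ydot[18] = k13 * y[16] - k14 * y[18];

    /* IgG: peripheral ASC excluded from the secreting pool */
    ydot[19] = ksin_igg * (y[14] + y[15] + y[16] + y[17]) - kdeg_igg * y[19];
}
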