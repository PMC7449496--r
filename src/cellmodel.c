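/* Compact iPSC-CM / adult-ventricular whole-cell electrophysiology model
 * for deSolve's compiled-code interface.
 *
 * State vector (13):
 *   0 V (mV)         membrane voltage
 *   1 m, 2 h, 3 j    fast sodium current gates
 *   4 d, 5 f, 6 fca  L-type calcium current gates
 *   7 xr             rapid delayed rectifier activation
 *   8 xs             slow delayed rectifier (IKs) activation
 *   9 xf             funny current activation
 *  10 Nai (mM)      11 Cai (mM)      12 Ki (mM)
 *
 * All currents are densities (pA/pF); time in ms.
 * One forcing function: injected noise current (pA/pF, depolarizing > 0).
 */

#include <math.h>
#include <R.h>

#define NPAR 27

static double parms[NPAR];
static double forc[1];

#define g_na        parms[0]
#define g_cal       parms[1]
#define g_kr        parms[2]
#define g_k1        parms[3]
#define g_f         parms[4]
#define g_ks        parms[5]
#define iks_x1      parms[6]
#define iks_x2      parms[7]
#define iks_x3      parms[8]
#define iks_x4      parms[9]
#define iks_x5      parms[10]
#define p_nak       parms[11]
#define k_ncx       parms[12]
#define g_bna       parms[13]
#define g_bca       parms[14]
#define g_pca       parms[15]
#define tausc_na    parms[16]
#define tausc_cal   parms[17]
#define tausc_kr    parms[18]
#define tausc_f     parms[19]
#define stim_amp    parms[20]
#define stim_dur    parms[21]
#define bcl         parms[22]
#define nao         parms[23]
#define ko          parms[24]
#define cao         parms[25]
#define conv        parms[26]   /* Cm/(F*Vc): mM per pA/pF per ms, monovalent */

#define i_noise     forc[0]

static double clexp(double x)
{
    if (x > 700.0) x = 700.0;
    if (x < -700.0) x = -700.0;
    return exp(x);
}

void cell_initmod(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, parms);
}

void cell_initforc(void (*odeforcs)(int *, double *))
{
    int n = 1;
    odeforcs(&n, forc);
}

void cell_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    const double RTF = 26.712338; /* mV at 310 K */

    double V = y[0];
    double m = y[1], h = y[2], j = y[3];
    double d = y[4], f = y[5], fca = y[6];
    double xr = y[7], xs = y[8], xf = y[9];
    double nai = y[10], cai = y[11], ki = y[12];

    if (nai < 1e-3) nai = 1e-3;
    if (cai < 1e-7) cai = 1e-7;
    if (ki < 1e-3) ki = 1e-3;

    double ena = RTF * log(nao / nai);
    double ek  = RTF * log(ko / ki);
    double eca = 0.5 * RTF * log(cao / cai);

    /* --- fast sodium current --- */
    double m_inf = 1.0 / pow(1.0 + clexp((-56.86 - V) / 9.03), 2.0);
    double am = 1.0 / (1.0 + clexp((-60.0 - V) / 5.0));
    double bm = 0.1 / (1.0 + clexp((V + 35.0) / 5.0)) +
                0.1 / (1.0 + clexp((V - 50.0) / 200.0));
    double tau_m = am * bm;
    double h_inf = 1.0 / pow(1.0 + clexp((V + 71.55) / 7.43), 2.0);
    double ah, bh, aj, bj;
    if (V < -40.0) {
        ah = 0.057 * clexp(-(V + 80.0) / 6.8);
        bh = 2.7 * clexp(0.079 * V) + 3.1e5 * clexp(0.3485 * V);
        aj = ((-2.5428e4 * clexp(0.2444 * V) - 6.948e-6 * clexp(-0.04391 * V)) *
              (V + 37.78)) / (1.0 + clexp(0.311 * (V + 79.23)));
        bj = 0.02424 * clexp(-0.01052 * V) /
             (1.0 + clexp(-0.1378 * (V + 40.14)));
    } else {
        ah = 0.0;
        bh = 0.77 / (0.13 * (1.0 + clexp(-(V + 10.66) / 11.1)));
        aj = 0.0;
        bj = 0.6 * clexp(0.057 * V) / (1.0 + clexp(-0.1 * (V + 32.0)));
    }
    double tau_h = 1.0 / (ah + bh);
    double tau_j = 1.0 / (aj + bj);
    double i_na = g_na * m * m * m * h * j * (V - ena);

    /* --- L-type calcium current (ohmic driving force, Ca-dependent
           inactivation via fca) --- */
    double d_inf = 1.0 / (1.0 + clexp(-(V + 9.0) / 7.0));
    double ad = 1.4 / (1.0 + clexp((-35.0 - V) / 13.0)) + 0.25;
    double bd = 1.4 / (1.0 + clexp((V + 5.0) / 5.0));
    double gd = 1.0 / (1.0 + clexp((50.0 - V) / 20.0));
    double tau_d = ad * bd + gd;
    double f_inf = 1.0 / (1.0 + clexp((V + 25.0) / 6.0));
    double tau_f = 150.0 + 900.0 * clexp(-(V + 25.0) * (V + 25.0) / 600.0);
    double fca_inf = 0.3 + 0.7 / (1.0 + (cai / 6e-4) * (cai / 6e-4));
    double tau_fca = 2.0;
    double i_cal = g_cal * d * f * fca * (V - 60.0);

    /* --- rapid delayed rectifier --- */
    double xr_inf = 1.0 / (1.0 + clexp(-(V + 14.1) / 6.5));
    double dv1 = V + 14.1, dv2 = V - 3.3328;
    double axr = (fabs(dv1) < 1e-6) ? 0.0015
               : 0.0003 * dv1 / (1.0 - clexp(-dv1 / 5.0));
    double bxr = (fabs(dv2) < 1e-6) ? 3.7862e-4
               : 7.3898e-5 * dv2 / (clexp(dv2 / 5.1237) - 1.0);
    double tau_xr = 1.0 / (axr + bxr);
    double rkr = 1.0 / (1.0 + clexp((V + 15.0) / 22.4));
    double i_kr = g_kr * sqrt(ko / 5.4) * xr * rkr * (V - ek);

    /* --- slow delayed rectifier (IKs), single activation gate squared --- */
    double xs_inf = 1.0 / (1.0 + (iks_x3 / iks_x1) *
                           clexp(V * (1.0 / iks_x4 - 1.0 / iks_x2)));
    double tau_xs = 1.0 / (iks_x1 * clexp(V / iks_x2) +
                           iks_x3 * clexp(V / iks_x4)) + iks_x5;
    double i_ks = g_ks * xs * xs * (V - ek);

    /* --- inward rectifier --- */
    double vk = V - ek;
    double ak1 = 1.02 / (1.0 + clexp(0.2385 * (vk - 59.215)));
    double bk1 = (0.49124 * clexp(0.08032 * (vk + 5.476)) +
                  clexp(0.06175 * (vk - 594.31))) /
                 (1.0 + clexp(-0.5143 * (vk + 4.753)));
    double i_k1 = g_k1 * sqrt(ko / 5.4) * ak1 / (ak1 + bk1) * vk;

    /* --- funny current, half Na / half K --- */
    double xf_inf = 1.0 / (1.0 + clexp((V + 77.0) / 5.0));
    double tau_xf = 1900.0 / (1.0 + clexp((V + 15.0) / 10.0)) + 15.0;
    double i_fna = 0.5 * g_f * xf * (V - ena);
    double i_fk  = 0.5 * g_f * xf * (V - ek);
    double i_f = i_fna + i_fk;

    /* --- pumps, exchanger, background --- */
    double i_nak = p_nak * (ko / (ko + 1.0)) * (nai / (nai + 40.0)) /
                   (1.0 + 0.1245 * clexp(-0.1 * V / RTF) +
                    0.0353 * clexp(-V / RTF));
    double e1 = clexp(0.35 * V / RTF);
    double e2 = clexp(-0.65 * V / RTF);
    double i_ncx = k_ncx *
        (e1 * nai * nai * nai * cao - e2 * nao * nao * nao * cai * 2.5) /
        ((669921.875 + nao * nao * nao) * (1.38 + cao) * (1.0 + 0.1 * e2));
    /* 669921.875 = 87.5^3 */
    double i_bna = g_bna * (V - ena);
    double i_bca = g_bca * (V - eca);
    double i_pca = g_pca * cai / (cai + 5e-4);

    /* --- pacing stimulus (assigned to K+ for ion bookkeeping) --- */
    double i_stim = 0.0;
    if (bcl > 0.0) {
        double tm = fmod(*t, bcl);
        if (tm < stim_dur) i_stim = stim_amp;
    }

    double i_ion = i_na + i_cal + i_kr + i_ks + i_k1 + i_f +
                   i_nak + i_ncx + i_bna + i_bca + i_pca;

    ydot[0] = -(i_ion + i_stim) + i_noise;
    ydot[1] = (m_inf - m) / (tau_m * tausc_na);
    ydot[2] = (h_inf - h) / (tau_h * tausc_na);
    ydot[3] = (h_inf - j) / (tau_j * tausc_na);
    ydot[4] = (d_inf - d) / (tau_d * tausc_cal);
    ydot[5] = (f_inf - f) / (tau_f * tausc_cal);
    ydot[6] = (fca_inf - fca) / tau_fca;
    ydot[7] = (xr_inf - xr) / (tau_xr * tausc_kr);
    ydot[8] = (xs_inf - xs) / tau_xs;
    ydot[9] = (xf_inf - xf) / (tau_xf * tausc_f);

    /* ion bookkeeping; buffered free calcium */
    double bufc = 0.06, kbufc = 7e-4;
    double buf = 1.0 / (1.0 + bufc * kbufc / ((cai + kbufc) * (cai + kbufc)));
    ydot[10] = -(i_na + i_bna + i_fna + 3.0 * i_nak + 3.0 * i_ncx) * conv;
    ydot[11] = -buf * (i_cal + i_bca + i_pca - 2.0 * i_ncx) * conv / 2.0;
    ydot[12] = -(i_kr + i_ks + i_k1 + i_fk - 2.0 * i_nak + i_stim) * conv;

    if (ip[0] >= 9) {
        yout[0] = i_na;
        yout[1] = i_cal;
        yout[2] = i_kr;
        yout[3] = i_ks;
        yout[4] = i_k1;
        yout[5] = i_f;
        yout[6] = i_nak;
        yout[7] = i_ncx;
        yout[8] = i_noise;
    }
}
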