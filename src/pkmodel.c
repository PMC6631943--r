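/* Compiled right-hand side of the site-dependent dissolution PK model,
 * used through deSolve's compiled-model interface.
 *
 * States (y):
 *   0 x_tablet  undissolved drug, fraction of dose
 *   1 x_lumen   dissolved drug in the lumen, fraction of dose
 *   2 x_gut     absorbable drug in the gut compartment, fraction of dose
 *   3 x1        drug amount in the central compartment, mg
 *   4 x2        drug amount in the peripheral compartment, mg
 *   5 x_elim    cumulative eliminated amount, mg (bookkeeping)
 *
 * Parameters (parms), in this order:
 *   vmax am50 imax t_get hill_stomach diss_max t_itt t_ctt hill_intestine
 *   k_lag k_a v1 v2 cl cld dose
 */
#include <R.h>
#include <Rinternals.h>
#include <math.h>

static double parms[16];

void sild_initmod(void (*odeparms)(int *, double *))
{
    int N = 16;
    odeparms(&N, parms);
}

/* Rising Hill fraction t^h / (t50^h + t^h), computed in overflow-safe
 * ratio form; continuous extension 0 at t <= 0. */
static double hill_frac(double t, double t50, double h)
{
    double r;
    if (t <= 0.0) return 0.0;
    r = pow(t50 / t, h);
    if (!R_FINITE(r)) return 0.0;
    return 1.0 / (1.0 + r);
}

void sild_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double vmax = parms[0], am50 = parms[1], imax = parms[2],
           t_get = parms[3], hs = parms[4], dmax = parms[5],
           t_itt = parms[6], t_ctt = parms[7], hi = parms[8],
           k_lag = parms[9], k_a = parms[10], v1 = parms[11],
           v2 = parms[12], cl = parms[13], cld = parms[14],
           dose = parms[15];
    double tt = *t;
    double t_trans1 = t_get + t_itt;
    double t_trans2 = t_get + t_itt + t_ctt;
    double fdiss = 1.0 - imax * hill_frac(tt, t_get, hs)
        + dmax * hill_frac(tt, t_trans1, hi)
               * (1.0 - hill_frac(tt, t_trans2, hi));
    double xt = y[0];
    double rate = (xt > 0.0) ? vmax * xt / (am50 + xt) * fdiss : 0.0;
    double c1 = y[3] / v1;
    double c2 = y[4] / v2;

    ydot[0] = -rate;
    ydot[1] = rate - k_lag * y[1];
    ydot[2] = k_lag * y[1] - k_a * y[2];
    ydot[3] = k_a * y[2] * dose - cld * c1 + cld * c2 - cl * c1;
    ydot[4] = cld * c1 - cld * c2;
    ydot[5] = cl * c1;

    if (ip[0] > 0)
        yout[0] = c1 * 1000.0;   /* central concentration, ng/mL */
}
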