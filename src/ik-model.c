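/* Compiled right-hand side of the two-compartment tumor model for use with
 * deSolve inside fitting loops.  States (uM): y[0] = q2 (surface-bound),
 * y[1] = q3 (internalized).  Plasma and (in data-driven mode) occupancy are
 * supplied as interpolated forcing functions.
 *
 * parms: [0] kon  - nonlinear: k_a expressed in uM^-1 h^-1; linear: k21_lin (h^-1)
 *        [1] ag   - total antigen, uM (ignored in linear variant)
 *        [2] kint - internalization rate, h^-1
 *        [3] keff - efflux rate, h^-1
 *        [4] linear   - 1: linear variant, 0: nonlinear
 *        [5] datamode - 1: occupancy from forcing, 0: occupancy = q2 + q3
 */
#include <R.h>

static double parms[6];
static double forc[2];

#define KON      parms[0]
#define AG       parms[1]
#define KINT     parms[2]
#define KEFF     parms[3]
#define LINEAR   parms[4]
#define DATAMODE parms[5]

void ik_initmod(void (*odeparms)(int *, double *))
{
    int n = 6;
    odeparms(&n, parms);
}

void ik_initforc(void (*odeforcs)(int *, double *))
{
    int n = 2;
    odeforcs(&n, forc);
}

void ik_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    double plasma = forc[0] > 0 ? forc[0] : 0;
    double occ = DATAMODE > 0.5 ? forc[1] : (y[0] + y[1]);
    double b;

    if (occ < 0) occ = 0;
    if (LINEAR > 0.5) {
        b = KON * plasma;
    } else {
        double free_ag = AG - occ;
        if (free_ag < 0) free_ag = 0;
        b = KON * free_ag * plasma;
    }
    ydot[0] = b - KINT * y[0];
    ydot[1] = KINT * y[0] - KEFF * y[1];
}
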