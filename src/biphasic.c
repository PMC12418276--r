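/* Two-compartment (biphasic matrix) release kinetics for deSolve.
 *
 * States: y[0] = N_lc origin pool, y[1] = N_lc transferred-from-hc pool,
 *         y[2] = N_hc pool (all moles).
 * Parameters: parms[0] = kappa_ex (1/s), parms[1] = N_lc0 (mol).
 * Forcing:    forc[0] = k(t), the release rate constant (1/s).
 */
#include <R.h>

static double parms[2];
static double forc[1];

void bip_init(void (*odeparms)(int *, double *))
{
    int N = 2;
    odeparms(&N, parms);
}

void bip_forc(void (*odeforcs)(int *, double *))
{
    int N = 1;
    odeforcs(&N, forc);
}

void bip_deriv(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    double k = forc[0];
    double N_lc = y[0] + y[1];
    double gate = 1.0 - N_lc / parms[1];
    if (gate < 0.0) gate = 0.0;
    double transfer = parms[0] * y[2] * gate;
    ydot[0] = -k * y[0];
    ydot[1] = transfer - k * y[1];
    ydot[2] = -transfer;
}
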