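/* Compiled right-hand sides for the relay neuron models, in the deSolve
 * compiled-model convention (initializer + derivs pair per model).  The
 * parameter packing order must match .pack_parms2 / .pack_parms3 in
 * R/simulator.R.  The modulating conductance s(t) = S0 + S1*sin(omega*t)
 * is evaluated here so that whole piecewise trajectories integrate in a
 * single solver call with pulse events handled by deSolve.
 */
#include <R.h>
#include <math.h>

static double p2[19];
static double p3[35];

static double sig_up(double v, double vhalf, double k)
{
    return 1.0 / (1.0 + exp(-(v - vhalf) / k));
}

static double sig_down(double v, double vhalf, double k)
{
    return 1.0 / (1.0 + exp((v - vhalf) / k));
}

void relay2_init(void (*odeparms)(int *, double *))
{
    int n = 19;
    odeparms(&n, p2);
}

void relay2_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    const double C_m = p2[0], g_T = p2[1], E_T = p2[2], g_L = p2[3],
                 E_L = p2[4], I_ext = p2[5], v_rev = p2[6], phi_h = p2[7];
    const double v = y[0], h = y[1];
    const double s = p2[16] + p2[17] * sin(p2[18] * (*t));
    const double pinf = sig_up(v, p2[8], p2[9]);
    const double hinf = sig_down(v, p2[10], p2[11]);
    const double tauh = p2[12] + p2[13] * exp(-(v - p2[14]) / p2[15]);
    const double I_T = g_T * pinf * pinf * h * (v - E_T);
    const double I_L = g_L * (v - E_L);

    ydot[0] = (-I_T - I_L + I_ext - s * (v - v_rev)) / C_m;
    ydot[1] = phi_h * (hinf - h) / tauh;
}

void relay3_init(void (*odeparms)(int *, double *))
{
    int n = 35;
    odeparms(&n, p3);
}

void relay3_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    const double C_m = p3[0], g_L = p3[1], E_L = p3[2], g_Na = p3[3],
                 E_Na = p3[4], g_K = p3[5], E_K = p3[6], g_T = p3[7],
                 E_T = p3[8], I_ext = p3[9], v_rev = p3[10], phi_h = p3[11],
                 phi_r = p3[12], k_n = p3[13];
    const double v = y[0], h = y[1], r = y[2];
    const double s = p3[32] + p3[33] * sin(p3[34] * (*t));
    const double minf = sig_up(v, p3[14], p3[15]);
    const double hinf = sig_down(v, p3[16], p3[17]);
    const double a_h = p3[18] * exp(-(v - p3[19]) / p3[20]);
    const double b_h = p3[21] / (1.0 + exp(-(v - p3[22]) / p3[23]));
    const double tauh = 1.0 / (a_h + b_h);
    const double pinf = sig_up(v, p3[24], p3[25]);
    const double rinf = sig_down(v, p3[26], p3[27]);
    const double taur = p3[28] + p3[29] * exp(-(v - p3[30]) / p3[31]);
    const double ngate = k_n * (1.0 - h);
    const double I_L = g_L * (v - E_L);
    const double I_Na = g_Na * minf * minf * minf * h * (v - E_Na);
    const double I_K = g_K * ngate * ngate * ngate * ngate * (v - E_K);
    const double I_T = g_T * pinf * pinf * r * (v - E_T);

    ydot[0] = (-I_L - I_Na - I_K - I_T + I_ext - s * (v - v_rev)) / C_m;
    ydot[1] = phi_h * (hinf - h) / tauh;
    ydot[2] = phi_r * (rinf - r) / taur;
}
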