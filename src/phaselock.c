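#include <R.h>
#include <math.h>

static double sigm(double V, double half, double slope)
{
    return 0.5 * (1.0 + tanh((V - half) / slope));
}

/* p: gCa gK gLeak ECa EK ELeak Vmh Vms Vwh Vws phi I0 */
static void ml_core(const double *p, double V, double w, double isyn,
                    double *dV, double *dw)
{
    double minf = sigm(V, p[6], p[7]);
    double winf = sigm(V, p[8], p[9]);
    *dV = -p[0] * minf * (V - p[3]) - p[1] * w * (V - p[4])
          - p[2] * (V - p[5]) + p[11] - isyn;
    *dw = p[10] * cosh((V - p[8]) / (2.0 * p[9])) * (winf - w);
}

static double tfun(double vpre, double half, double scale)
{
    return 1.0 / (1.0 + exp(-(vpre - half) * scale));
}

/* ---- single free-running neuron: y = (V, w) ---- */
static double p1[12];
void init_ml1(void (*odeparms)(int *, double *)) { int n = 12; odeparms(&n, p1); }
void deriv_ml1(int *neq, double *t, double *y, double *ydot, double *yout, int *ip)
{
    ml_core(p1, y[0], y[1], 0.0, ydot, ydot + 1);
}

/* ---- neuron + one synapse driven by forced presynaptic voltage ----
   y = (V, w, s); parms: 12 neuron + gsyn Esyn alpha beta Thalf Tscale */
static double p2[18];
static double f2[1];
void init_mlstim(void (*odeparms)(int *, double *)) { int n = 18; odeparms(&n, p2); }
void forc_mlstim(void (*odeforcs)(int *, double *)) { int n = 1; odeforcs(&n, f2); }
void deriv_mlstim(int *neq, double *t, double *y, double *ydot, double *yout, int *ip)
{
    double T = tfun(f2[0], p2[16], p2[17]);
    double isyn = p2[12] * y[2] * (y[0] - p2[13]);
    ml_core(p2, y[0], y[1], isyn, ydot, ydot + 1);
    ydot[2] = p2[14] * T * (1.0 - y[2]) - p2[15] * y[2];
}

/* ---- three-neuron network ----
   y = (V1 w1 V2 w2 V3 w3 s12 s32 s23)
   parms: neuron1[0:11] neuron2[12:23] neuron3[24:35]
          g12 E12 g32 E32 g23 E23 alpha beta Thalf Tscale  [36:45] */
static double pN[46];
void init_net3(void (*odeparms)(int *, double *)) { int n = 46; odeparms(&n, pN); }
void deriv_net3(int *neq, double *t, double *y, double *ydot, double *yout, int *ip)
{
    double a = pN[42], b = pN[43], Th = pN[44], Ts = pN[45];
    double isyn2 = pN[36] * y[6] * (y[2] - pN[37]) + pN[38] * y[7] * (y[2] - pN[39]);
    double isyn3 = pN[40] * y[8] * (y[4] - pN[41]);
    ml_core(pN,      y[0], y[1], 0.0,   ydot,     ydot + 1);
    ml_core(pN + 12, y[2], y[3], isyn2, ydot + 2, ydot + 3);
    ml_core(pN + 24, y[4], y[5], isyn3, ydot + 4, ydot + 5);
    ydot[6] = a * tfun(y[0], Th, Ts) * (1.0 - y[6]) - b * y[6];
    ydot[7] = a * tfun(y[4], Th, Ts) * (1.0 - y[7]) - b * y[7];
    ydot[8] = a * tfun(y[2], Th, Ts) * (1.0 - y[8]) - b * y[8];
}
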