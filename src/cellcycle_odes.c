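/* Compiled right-hand sides for the cell-cycle oscillator models,
 * using deSolve's compiled-function interface. */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

/* ---- two-ODE Cdk1/cyclin B relaxation oscillator ----------------------
 * parms (20): ks kd ka ki eps
 *             d: basal max ec50 n dir
 *             a: basal max ec50 n dir
 *             i: basal max ec50 n dir
 * dir = +1 increasing in cdk1a, -1 decreasing.
 */
static double parms2[20];
#define KS    parms2[0]
#define KD    parms2[1]
#define KA    parms2[2]
#define KI    parms2[3]
#define EPS   parms2[4]

void initmod_twoode(void (*odeparms)(int *, double *))
{
    int n = 20;
    odeparms(&n, parms2);
}

static double hill(const double *h, double x)
{
    /* h: basal max ec50 n dir */
    double basal = h[0], hmax = h[1], ec50 = h[2], nh = h[3], dir = h[4];
    double xn, en, frac;
    if (x < 0.0) x = 0.0;
    xn = pow(x, nh);
    en = pow(ec50, nh);
    frac = (dir > 0.0) ? xn / (en + xn) : en / (en + xn);
    return basal + (hmax - basal) * frac;
}

void derivs_twoode(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    double cyc = y[0], cdk = y[1];
    double d = hill(parms2 + 5, cdk);
    double a = hill(parms2 + 10, cdk);
    double i = hill(parms2 + 15, cdk);
    ydot[0] = KS - KD * d * cyc;
    ydot[1] = (KA * a * (cyc - cdk) - KI * i * cdk) / EPS;
}

/* ---- five-ODE mass-action Cdk1/Greatwall/PP2A/APC system --------------
 * states: c (cyclin B-Cdk1), g (active Greatwall), s (free phospho-ENSA),
 *         y (PP2A:ENSA-P complex), a (active APC/C)
 * parms (14): ks kd k1 k2 kb k3 kass kcat k5 k6 Gtot Stot Ptot Atot
 */
static double parms5[14];

void initmod_fiveode(void (*odeparms)(int *, double *))
{
    int n = 14;
    odeparms(&n, parms5);
}

void derivs_fiveode(int *neq, double *t, double *yv, double *ydot,
                    double *yout, int *ip)
{
    double ks = parms5[0], kd = parms5[1], k1 = parms5[2], k2 = parms5[3],
           kb = parms5[4], k3 = parms5[5], kass = parms5[6],
           kcat = parms5[7], k5 = parms5[8], k6 = parms5[9],
           Gtot = parms5[10], Stot = parms5[11], Ptot = parms5[12],
           Atot = parms5[13];
    double c = yv[0], g = yv[1], s = yv[2], yc = yv[3], a = yv[4];
    double pfree = Ptot - yc;     /* free, active PP2A */
    double su = Stot - s - yc;    /* unphosphorylated ENSA */

    ydot[0] = ks - kd * a * c;
    ydot[1] = k1 * c * (Gtot - g) - k2 * pfree * g - kb * g;
    ydot[2] = k3 * g * su - kass * s * pfree;
    ydot[3] = kass * s * pfree - kcat * yc;
    ydot[4] = k5 * c * (Atot - a) - k6 * pfree * a;
}

static const R_CMethodDef CEntries[] = {
    {"initmod_twoode",  (DL_FUNC) &initmod_twoode,  1},
    {"derivs_twoode",   (DL_FUNC) &derivs_twoode,   6},
    {"initmod_fiveode", (DL_FUNC) &initmod_fiveode, 1},
    {"derivs_fiveode",  (DL_FUNC) &derivs_fiveode,  6},
    {NULL, NULL, 0}
};

void R_init_thermocycle(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
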