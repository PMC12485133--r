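/* Generic mass-action ODE right-hand side and Jacobian for deSolve.
 *
 * Parameter vector layout (all doubles):
 *   p[0]              number of species  (ns)
 *   p[1]              number of reactions (nr)
 *   p[2 .. 2+3*nr-1]  per reaction: rate constant k, reactant index r1
 *                     (1-based), reactant index r2 (0 = unimolecular)
 *   p[2+3*nr .. ]     stoichiometry matrix S (ns x nr), column-major
 *
 * Reaction velocity: v_j = k_j * y[r1] * (r2 ? y[r2] : 1); ydot = S v.
 */

#include <R.h>
#include <R_ext/Rdynload.h>

#define MA_MAX_PARMS 4096

static double ma_parms[MA_MAX_PARMS];

void ma_init(void (*odeparms)(int *, double *))
{
    int n = MA_MAX_PARMS;
    odeparms(&n, ma_parms);
}

void ma_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    const int ns = (int) ma_parms[0];
    const int nr = (int) ma_parms[1];
    const double *rx = ma_parms + 2;        /* 3 doubles per reaction */
    const double *S  = ma_parms + 2 + 3 * nr;
    int i, j;

    for (i = 0; i < ns; i++) ydot[i] = 0.0;
    for (j = 0; j < nr; j++) {
        const double k = rx[3 * j];
        const int r1 = (int) rx[3 * j + 1];
        const int r2 = (int) rx[3 * j + 2];
        double v = k * y[r1 - 1];
        if (r2 > 0) v *= y[r2 - 1];
        const double *Sj = S + (size_t) j * ns;
        for (i = 0; i < ns; i++) ydot[i] += Sj[i] * v;
    }
}

void ma_jac(int *neq, double *t, double *y, int *ml, int *mu,
            double *pd, int *nrowpd, double *yout, int *ip)
{
    const int ns = (int) ma_parms[0];
    const int nr = (int) ma_parms[1];
    const double *rx = ma_parms + 2;
    const double *S  = ma_parms + 2 + 3 * nr;
    const int nrow = *nrowpd;
    int i, j;

    for (i = 0; i < nrow * ns; i++) pd[i] = 0.0;
    for (j = 0; j < nr; j++) {
        const double k = rx[3 * j];
        const int r1 = (int) rx[3 * j + 1] - 1;
        const int r2 = (int) rx[3 * j + 2] - 1;
        const double *Sj = S + (size_t) j * ns;
        if (r2 < 0) {
            /* dv/dy[r1] = k */
            for (i = 0; i < ns; i++) pd[r1 * nrow + i] += Sj[i] * k;
        } else {
            for (i = 0; i < ns; i++) {
                pd[r1 * nrow + i] += Sj[i] * k * y[r2];
                pd[r2 * nrow + i] += Sj[i] * k * y[r1];
            }
        }
    }
}
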