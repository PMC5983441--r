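/* Compiled Hill-kinetics right-hand side for deSolve.
 *
 * A compiled network is flattened into the deSolve parameter vector:
 *   p[0] nnode, p[1] nin, p[2] a, p[3] b, p[4] S, p[5] n,
 *   p[6 .. 6+nnode-1]                per-node degradation rates k
 *   p[6+nnode .. 6+nnode+nin-1]      constant input levels
 *   then Mact (nnode x (nnode+nin), column-major)
 *   then Minh (nnode x (nnode+nin), column-major)
 * Mact[i,j] = 1 when extended species j activates node i (ditto Minh for
 * inhibition).  Extended species = nodes followed by inputs.
 *
 * dx_i/dt = a * sum_j Mact[i,j] * x_j^n/(S^n + x_j^n)
 *         + b * sum_j Minh[i,j] * S^n/(S^n + x_j^n)
 *         - k_i * x_i
 *
 * State values are clipped at 0 inside the Hill terms so that tiny
 * negative solver excursions cannot produce NaN for fractional powers.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define GRN_MAX_PARMS 8192
#define GRN_MAX_EXT   256

static double grn_parms[GRN_MAX_PARMS];

void grn_initmod(void (*odeparms)(int *, double *))
{
    int n = GRN_MAX_PARMS;
    odeparms(&n, grn_parms);
}

void grn_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const double *p = grn_parms;
    int nnode = (int) p[0];
    int nin   = (int) p[1];
    double a  = p[2];
    double b  = p[3];
    double S  = p[4];
    double n  = p[5];
    const double *k    = p + 6;
    const double *inp  = p + 6 + nnode;
    int next = nnode + nin;
    const double *Mact = p + 6 + nnode + nin;
    const double *Minh = Mact + (size_t) nnode * next;

    double fa[GRN_MAX_EXT], fi[GRN_MAX_EXT];
    double Sn = pow(S, n);

    for (int j = 0; j < next; j++) {
        double x = (j < nnode) ? y[j] : inp[j - nnode];
        if (x < 0.0) x = 0.0;
        double xn = pow(x, n);
        fa[j] = xn / (Sn + xn);
        fi[j] = Sn / (Sn + xn);
    }

    for (int i = 0; i < nnode; i++) {
        double s = -k[i] * y[i];
        for (int j = 0; j < next; j++) {
            /* column-major: element (i, j) at j*nnode + i */
            double ma = Mact[(size_t) j * nnode + i];
            double mi = Minh[(size_t) j * nnode + i];
            if (ma != 0.0) s += a * ma * fa[j];
            if (mi != 0.0) s += b * mi * fi[j];
        }
        ydot[i] = s;
    }
}

static const R_CMethodDef cMethods[] = {
    {"grn_initmod", (DL_FUNC) &grn_initmod, 1, NULL},
    {"grn_derivs",  (DL_FUNC) &grn_derivs,  6, NULL},
    {NULL, NULL, 0, NULL}
};

void R_init_ageingGRN(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
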