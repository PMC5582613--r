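/* Compiled right-hand side of the 8-species MeIQx metabolism model for the
 * deSolve compiled-model interface.  Species order:
 *   y[0] meiqx            y[1] c_hydroxy_meiqx   y[2] meiqx_n2_gl
 *   y[3] meiqx_n2_so3h    y[4] oxo_meiqx         y[5] honh_meiqx
 *   y[6] hon_meiqx_n2_gl  y[7] potential_genotoxic
 * Parameter vector (24, order fixed, see as_parm_vector() on the R side):
 *   0 k1  1 k2  2 k3  3 k4  4 km1  5 km2  6 km3  7 km4
 *   8 vm_so3h  9 km_so3h  10 vm_oxo  11 km_oxo  12 vm_pgc  13 km_pgc
 *   14 e_cyp1a2_total  15 e_ugt_total
 *   16 a1 17 b1 18 theta1 19 n1   (alpha sigmoid; saturation mode has a1 = 0)
 *   20 a2 21 b2 22 theta2 23 n2   (beta sigmoid)
 * Concentrations in M, time in h.  States are clipped at 0 for rate
 * evaluation only; the solver state itself is never modified.
 */
#include <R.h>
#include <math.h>

static double parms[24];

void meiqx_initmod(void (*odeparms)(int *, double *))
{
    int n = 24;
    odeparms(&n, parms);
}

static double sigmoid_c(double a, double b, double theta, double n, double s)
{
    if (a == 0.0) return b;          /* saturation sub-model, theta may be 0 */
    double tn = pow(theta, n);
    return a * tn / (tn + pow(s, n)) + b;
}

static double mm(double vmax, double km, double s)
{
    return vmax * s / (km + s);
}

void meiqx_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double S = y[0] > 0.0 ? y[0] : 0.0;   /* MeIQx */
    double H = y[5] > 0.0 ? y[5] : 0.0;   /* HONH-MeIQx */

    double alpha = sigmoid_c(parms[16], parms[17], parms[18], parms[19], S);
    double beta  = sigmoid_c(parms[20], parms[21], parms[22], parms[23], S);

    double ecyp = parms[14], eugt = parms[15];

    double v1 = mm(parms[0] * alpha * ecyp, parms[4], S);  /* -> C-Hydroxy   */
    double v2 = mm(parms[1] * (1.0 - alpha) * ecyp, parms[5], S); /* -> HONH */
    double v3 = mm(parms[2] * beta * eugt, parms[6], S);   /* -> N2-Gl       */
    double v4 = mm(parms[3] * (1.0 - beta) * eugt, parms[7], H); /* -> HON-Gl*/
    double v5 = mm(parms[8],  parms[9],  S);               /* -> N2-SO3H     */
    double v6 = mm(parms[10], parms[11], S);               /* -> oxo         */
    double v7 = mm(parms[12], parms[13], H);               /* -> PGC         */

    ydot[0] = -(v1 + v2 + v3 + v5 + v6);
    ydot[1] = v1;
    ydot[2] = v3;
    ydot[3] = v5;
    ydot[4] = v6;
    ydot[5] = v2 - v4 - v7;
    ydot[6] = v4;
    ydot[7] = v7;
}
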