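/* Vectorised right-hand side of the coupled Hodgkin-Huxley network,
 * evaluated by deSolve's Runge-Kutta solvers as a compiled model.
 *
 * State layout: y = (V_1..V_N, n_1..n_N, m_1..m_N, h_1..h_N).
 * Parameters are pushed from R through hhnet_set_params() before each
 * integration window (the coupling matrix changes between windows):
 *   p[0]    N
 *   p[1..8] gNa, gK, gL, ENa, EK, EL, CM, Vrest
 *   p[9          .. 9+N-1]    Iext per neuron (muA/cm^2)
 *   p[9+N        .. 9+2N-1]   coupling strength c_i = eps/N_eta_i
 *   p[9+2N       .. 9+2N+N*N-1] graph Laplacian A (column-major, a_ii = -k_i)
 */
#include <R.h>
#include <Rinternals.h>
#include <math.h>

static double *gp = NULL;
static R_xlen_t gp_len = 0;

SEXP hhnet_set_params(SEXP pars)
{
    R_xlen_t n = XLENGTH(pars);
    if (gp != NULL) {
        R_Free(gp);
        gp = NULL;
        gp_len = 0;
    }
    gp = R_Calloc(n, double);
    memcpy(gp, REAL(pars), (size_t) n * sizeof(double));
    gp_len = n;
    return R_NilValue;
}

/* s / (exp(s) - 1) with the removable singularity at s = 0 */
static double rexpm1_ratio(double s)
{
    if (fabs(s) < 1e-8)
        return 1.0 - 0.5 * s;
    return s / expm1(s);
}

void hhnet_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    if (gp == NULL)
        error("hhnet parameters not initialised");
    const int N = (int) gp[0];
    if (*neq != 4 * N)
        error("state length %d does not match N = %d", *neq, N);
    const double gNa = gp[1], gK = gp[2], gL = gp[3];
    const double ENa = gp[4], EK = gp[5], EL = gp[6];
    const double CM = gp[7], Vrest = gp[8];
    const double *Iext = gp + 9;
    const double *cv = gp + 9 + N;
    const double *lap = gp + 9 + 2 * N;
    const double *V = y, *n = y + N, *m = y + 2 * N, *h = y + 3 * N;

    for (int i = 0; i < N; i++) {
        double icpl = 0.0;
        if (cv[i] != 0.0) {
            double acc = 0.0;
            const double *col = lap + i; /* row i, column-major stride N */
            for (int j = 0; j < N; j++)
                acc += col[(R_xlen_t) j * N] * V[j];
            icpl = cv[i] * acc;
        }
        const double u = V[i] - Vrest;
        const double an = 0.1 * rexpm1_ratio((10.0 - u) / 10.0);
        const double bn = 0.125 * exp(-u / 80.0);
        const double am = rexpm1_ratio((25.0 - u) / 10.0);
        const double bm = 4.0 * exp(-u / 18.0);
        const double ah = 0.07 * exp(-u / 20.0);
        const double bh = 1.0 / (exp((30.0 - u) / 10.0) + 1.0);

        const double m3h = m[i] * m[i] * m[i] * h[i];
        const double n4 = n[i] * n[i] * n[i] * n[i];
        ydot[i] = (-gNa * m3h * (V[i] - ENa)
                   - gK * n4 * (V[i] - EK)
                   - gL * (V[i] - EL)
                   + Iext[i] + icpl) / CM;
        ydot[N + i] = an * (1.0 - n[i]) - bn * n[i];
        ydot[2 * N + i] = am * (1.0 - m[i]) - bm * m[i];
        ydot[3 * N + i] = ah * (1.0 - h[i]) - bh * h[i];
    }
}
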