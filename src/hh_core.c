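/* Hodgkin-Huxley membrane model with Boltzmann-parameterised Na gating.
 *
 * State: y = (V [mV], m, h, n).  Parameter block (14 doubles):
 *   0 gL   1 gK   2 gNa   [mS/cm^2]
 *   3 EL   4 EK   5 ENa   [mV]
 *   6 Cm   [uF/cm^2]
 *   7 Vt   [mV]  rate-function threshold offset
 *   8 V2m  9 sm  10 V2h  11 sh   [mV] Boltzmann steady states for m, h
 *  12 hshift [mV] voltage shift applied to the h rate functions (tau_h only)
 *  13 Istim  [uA/cm^2]
 *
 * m and h relax toward their Boltzmann steady states with time constants
 * 1/(alpha+beta) from Traub-type rate functions; n keeps the full baseline
 * alpha/beta kinetics.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define NPAR 14

static double P[NPAR];

void hh_initmod(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, P);
}

/* u / (1 - exp(-u)) with the removable singularity at u = 0 */
static double xoverexpm(double u)
{
    return fabs(u) < 1e-8 ? 1.0 + 0.5 * u : u / (-expm1(-u));
}

/* u / (exp(u) - 1) */
static double xoverexpp(double u)
{
    return fabs(u) < 1e-8 ? 1.0 - 0.5 * u : u / expm1(u);
}

static void hh_rhs(const double *p, const double *y, double *d)
{
    double V = y[0], m = y[1], h = y[2], n = y[3];
    double vr = V - p[7];
    double am = 1.28 * xoverexpm((vr - 13.0) / 4.0);
    double bm = 1.40 * xoverexpp((vr - 40.0) / 5.0);
    double an = 0.16 * xoverexpm((vr - 15.0) / 5.0);
    double bn = 0.5 * exp(-(vr - 10.0) / 40.0);
    double vh = V - p[12] - p[7];
    double ah = 0.128 * exp(-(vh - 17.0) / 18.0);
    double bh = 4.0 / (1.0 + exp(-(vh - 40.0) / 5.0));
    double minf = 1.0 / (1.0 + exp(-(V - p[8]) / p[9]));
    double hinf = 1.0 / (1.0 + exp(-(V - p[10]) / p[11]));

    d[0] = (p[13]
            - p[0] * (V - p[3])
            - p[2] * m * m * m * h * (V - p[5])
            - p[1] * n * n * n * n * (V - p[4])) / p[6];
    d[1] = (minf - m) * (am + bm);
    d[2] = (hinf - h) * (ah + bh);
    d[3] = an * (1.0 - n) - bn * n;
}

/* deSolve entry point (compiled model) */
void hh_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    hh_rhs(P, y, ydot);
}

static void rk4_step(const double *p, double *y, double dt)
{
    double k1[4], k2[4], k3[4], k4[4], tmp[4];
    int i;
    hh_rhs(p, y, k1);
    for (i = 0; i < 4; i++) tmp[i] = y[i] + 0.5 * dt * k1[i];
    hh_rhs(p, tmp, k2);
    for (i = 0; i < 4; i++) tmp[i] = y[i] + 0.5 * dt * k2[i];
    hh_rhs(p, tmp, k3);
    for (i = 0; i < 4; i++) tmp[i] = y[i] + dt * k3[i];
    hh_rhs(p, tmp, k4);
    for (i = 0; i < 4; i++)
        y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

/* Fixed-step RK4 trajectory.  Returns (nkeep+1) x 4 matrix including the
 * initial state; every `thin`-th step is kept. */
SEXP C_hh_rk4(SEXP y0_, SEXP parms_, SEXP dt_, SEXP nsteps_, SEXP thin_)
{
    double y[4];
    const double *p = REAL(parms_);
    double dt = asReal(dt_);
    R_xlen_t nsteps = (R_xlen_t) asReal(nsteps_);
    int thin = asInteger(thin_);
    R_xlen_t nkeep = nsteps / thin, row = 1, s;
    SEXP out = PROTECT(allocMatrix(REALSXP, nkeep + 1, 4));
    double *o = REAL(out);
    int i;

    if (LENGTH(parms_) != NPAR) error("parameter block must have %d values", NPAR);
    for (i = 0; i < 4; i++) {
        y[i] = REAL(y0_)[i];
        o[i * (nkeep + 1)] = y[i];
    }
    for (s = 1; s <= nsteps; s++) {
        rk4_step(p, y, dt);
        if (!R_FINITE(y[0])) {
            UNPROTECT(1);
            error("non-finite membrane potential at t = %g ms", s * dt);
        }
        if (s % thin == 0) {
            for (i = 0; i < 4; i++) o[i * (nkeep + 1) + row] = y[i];
            row++;
        }
    }
    UNPROTECT(1);
    return out;
}

/* Continuation sweep over a stimulus grid.  For each stimulus value the
 * model is integrated from the previous final state (settle + analysis
 * window); V extrema and threshold-crossing spike counts are recorded over
 * the window.  Returns list(summary = nI x 4 matrix [vmin, vmax, nspikes,
 * ok], state = final state). */
SEXP C_hh_sweep(SEXP y0_, SEXP parms_, SEXP igrid_, SEXP settle_,
                SEXP window_, SEXP dt_, SEXP vthresh_, SEXP refract_)
{
    double p[NPAR], y[4];
    double dt = asReal(dt_), vthr = asReal(vthresh_), refr = asReal(refract_);
    R_xlen_t nset = (R_xlen_t) ceil(asReal(settle_) / dt);
    R_xlen_t nwin = (R_xlen_t) ceil(asReal(window_) / dt);
    int nI = LENGTH(igrid_), i, k;
    SEXP out = PROTECT(allocMatrix(REALSXP, nI, 4));
    SEXP fin = PROTECT(allocVector(REALSXP, 4));
    SEXP res = PROTECT(allocVector(VECSXP, 2));
    double *o = REAL(out);
    int ok = 1;

    if (LENGTH(parms_) != NPAR) error("parameter block must have %d values", NPAR);
    memcpy(p, REAL(parms_), NPAR * sizeof(double));
    memcpy(y, REAL(y0_), 4 * sizeof(double));

    for (i = 0; i < nI; i++) {
        double vmin = R_PosInf, vmax = R_NegInf, tlast = R_NegInf;
        double nspk = 0, vprev;
        R_xlen_t s;
        p[13] = REAL(igrid_)[i];
        if (ok) {
            for (s = 0; s < nset; s++) {
                rk4_step(p, y, dt);
                if (!R_FINITE(y[0])) { ok = 0; break; }
            }
            vprev = y[0];
            for (s = 0; s < nwin && ok; s++) {
                rk4_step(p, y, dt);
                if (!R_FINITE(y[0])) { ok = 0; break; }
                if (y[0] < vmin) vmin = y[0];
                if (y[0] > vmax) vmax = y[0];
                if (vprev < vthr && y[0] >= vthr && (s * dt - tlast) >= refr) {
                    nspk += 1.0;
                    tlast = s * dt;
                }
                vprev = y[0];
            }
        }
        o[i] = ok ? vmin : NA_REAL;
        o[nI + i] = ok ? vmax : NA_REAL;
        o[2 * nI + i] = ok ? nspk : NA_REAL;
        o[3 * nI + i] = ok;
        R_CheckUserInterrupt();
    }
    for (k = 0; k < 4; k++) REAL(fin)[k] = y[k];
    SET_VECTOR_ELT(res, 0, out);
    SET_VECTOR_ELT(res, 1, fin);
    UNPROTECT(3);
    return res;
}

static const R_CallMethodDef callMethods[] = {
    {"C_hh_rk4",   (DL_FUNC) &C_hh_rk4,   5},
    {"C_hh_sweep", (DL_FUNC) &C_hh_sweep, 8},
    {NULL, NULL, 0}
};

void R_init_nav11dyn(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, callMethods, NULL, NULL);
    /* hh_derivs / hh_initmod are resolved dynamically by deSolve */
    R_useDynamicSymbols(dll, TRUE);
}
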