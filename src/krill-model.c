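/* Stage-structured krill model: right-hand side for deSolve's compiled
 * interface.  State y = (L, J, A); transitions between stages open only
 * inside smooth periodic activation windows; reproduction follows the
 * generalized Deriso-Schnute function.
 *
 * Parameter vector (see R/simulate.R, .pack_parms()):
 *   [0] gamma   [1] r      [2] tau    [3] m_exp  [4] L_max
 *   [5] G_max   [6] m_L    [7] m_J    [8] m_A    [9] n_anom (0 = none)
 *   [10 .. 10+NMAX-1]        delta_L by anomaly year (1-based year -> idx 0)
 *   [10+NMAX .. 10+2*NMAX-1] delta_J by anomaly year
 */
#include <R.h>
#include <math.h>

#define NMAX 64
#define NPARMS (10 + 2 * NMAX)

static double parms[NPARMS];

void krill_init(void (*odeparms)(int *, double *))
{
    int N = NPARMS;
    odeparms(&N, parms);
}

/* smooth dome-shaped window, period 1, max 1 at t = t0 + integer */
static double activation(double t, double t0, double tau, double m_exp)
{
    double s = sin(M_PI * (t - t0)) / sin(M_PI * tau / 2.0);
    return exp(-pow(s * s, m_exp) * M_LN2);
}

static double recruitment(double A, double gamma, double Lmax, double Gmax)
{
    double x = Lmax * A;
    if (A <= 0.0)
        return 0.0;
    if (gamma > -1e-4) {                       /* Ricker limit, gamma -> 0- */
        return x * exp(-x / (M_E * Gmax));
    } else if (fabs(gamma + 1.0) < 1e-8) {     /* Beverton-Holt, beta = -1 */
        return x / (1.0 + x / Gmax);
    } else {
        double beta = gamma / pow(gamma + 1.0, 1.0 + 1.0 / gamma);
        return x * pow(1.0 - beta * x / Gmax, 1.0 / gamma);
    }
}

static void rhs_core(double t, const double *y, double *ydot, const double *pv)
{
    double gamma = pv[0], r = pv[1], tau = pv[2], m_exp = pv[3];
    double Lmax = pv[4], Gmax = pv[5];
    double mL = pv[6], mJ = pv[7], mA = pv[8];
    int n_anom = (int) pv[9];
    /* negativity guard: clip inside the RHS, keeps the field smooth */
    double L = y[0] > 0.0 ? y[0] : 0.0;
    double J = y[1] > 0.0 ? y[1] : 0.0;
    double A = y[2] > 0.0 ? y[2] : 0.0;

    if (n_anom > 0) {
        /* larval window of anomaly year Y (1-based): t in [Y-1-2/12, Y-1+10/12)
         * juvenile window:                           t in [Y-1-5/12, Y-1+7/12) */
        int iL = (int) floor(t + 2.0 / 12.0 + 1e-12);
        int iJ = (int) floor(t + 5.0 / 12.0 + 1e-12);
        if (iL >= 0 && iL < n_anom) mL *= exp(pv[10 + iL]);
        if (iJ >= 0 && iJ < n_anom) mJ *= exp(pv[10 + NMAX + iJ]);
    }

    {
        double f_sum = activation(t, 0.0, tau, m_exp);
        double f_spr = activation(t, 9.0 / 12.0, tau, m_exp);
        double f_wnt = activation(t, 0.5, tau, m_exp);
        double R = recruitment(A, gamma, Lmax, Gmax);

        ydot[0] = R * f_sum - r * f_spr * L - mL * L;
        ydot[1] = r * f_spr * L - r * f_wnt * J - mJ * J;
        ydot[2] = r * f_wnt * J - mA * A;
    }
}

void krill_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    rhs_core(*t, y, ydot, parms);
}

/* Weighted log-scale data term of the fitting cost, computed on the RK4
 * fast path: (1/n) sum_Y sum_j w_j (logobs_{Y,j} - log max(y_j(Y), eps))^2 */
void krill_cost(double *pv, double *y0, int *nyears, int *steps_per_year,
                double *logobs /* nyears x 3, column-major */, double *w,
                double *cost)
{
    int ny = *nyears, spy = *steps_per_year;
    double h = 1.0 / spy;
    double y[3] = { y0[0], y0[1], y0[2] };
    double k1[3], k2[3], k3[3], k4[3], ytmp[3];
    double acc = 0.0;

    for (int yr = 0; yr < ny; yr++) {
        for (int j = 0; j < 3; j++) {
            double v = y[j] > 1e-12 ? y[j] : 1e-12;
            double d = logobs[j * ny + yr] - log(v);
            acc += w[j] * d * d;
        }
        if (yr == ny - 1) break;
        for (int s = 0; s < spy; s++) {
            double t = (double) yr + (double) s * h;
            rhs_core(t, y, k1, pv);
            for (int i = 0; i < 3; i++) ytmp[i] = y[i] + 0.5 * h * k1[i];
            rhs_core(t + 0.5 * h, ytmp, k2, pv);
            for (int i = 0; i < 3; i++) ytmp[i] = y[i] + 0.5 * h * k2[i];
            rhs_core(t + 0.5 * h, ytmp, k3, pv);
            for (int i = 0; i < 3; i++) ytmp[i] = y[i] + h * k3[i];
            rhs_core(t + h, ytmp, k4, pv);
            for (int i = 0; i < 3; i++) {
                y[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
                if (y[i] < 0.0) y[i] = 0.0;
            }
        }
    }
    *cost = acc / ny;
}

/* Fixed-step classical RK4 over [0, nyears - 1], recording the state at
 * every integer time (1 January).  Fast path for the fitting drivers;
 * accuracy vs the adaptive solver is ~1e-5 relative at 72 steps/year. */
void krill_jan1(double *pv, double *y0, int *nyears, int *steps_per_year,
                double *out /* nyears x 3, column-major */)
{
    int ny = *nyears, spy = *steps_per_year;
    double h = 1.0 / spy;
    double y[3] = { y0[0], y0[1], y0[2] };
    double k1[3], k2[3], k3[3], k4[3], ytmp[3];
    long step = 0;

    for (int yr = 0; yr < ny; yr++) {
        out[yr] = y[0];
        out[ny + yr] = y[1];
        out[2 * ny + yr] = y[2];
        if (yr == ny - 1) break;
        for (int s = 0; s < spy; s++, step++) {
            double t = (double) yr + (double) s * h;
            rhs_core(t, y, k1, pv);
            for (int i = 0; i < 3; i++) ytmp[i] = y[i] + 0.5 * h * k1[i];
            rhs_core(t + 0.5 * h, ytmp, k2, pv);
            for (int i = 0; i < 3; i++) ytmp[i] = y[i] + 0.5 * h * k2[i];
            rhs_core(t + 0.5 * h, ytmp, k3, pv);
            for (int i = 0; i < 3; i++) ytmp[i] = y[i] + h * k3[i];
            rhs_core(t + h, ytmp, k4, pv);
            for (int i = 0; i < 3; i++) {
                y[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
                if (y[i] < 0.0) y[i] = 0.0;
            }
        }
    }
}
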