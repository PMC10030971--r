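/* Consumer-resource dynamics (Monod kinetics) for deSolve's compiled-code
 * interface.  The parameter vector is fetched through get_deSolve_gparms()
 * so that trait matrices of arbitrary size can be passed without fixed-size
 * static storage.
 *
 * Parameter vector layout (doubles):
 *   [0] n_consumers  [1] n_resources  [2] m  [3] D
 *   [4] essential (0 = substitutable, 1 = essential/Liebig)
 *   [5] supply_on    [6] mortality_on
 *   [7] pulse survival fraction e^(-m T)
 *   [8] additive dialect (0 = serial transfer, 1 = additive)
 *   [9] dilute_cells at pulse (0/1)
 *   [10 .. 10+nr)          supply concentrations S_j
 *   [10+nr .. 10+2nr)      per-pulse resource input D S_j T
 *   then mu_max, k_s, quota, each nc*nr column-major (index i + nc*j).
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

#define MAX_CONSUMERS 256

static SEXP gparms = NULL;

void crm_init(void (*odeparms)(int *, double *))
{
    static SEXP (*get_gparms)(void) = NULL;
    if (get_gparms == NULL)
        get_gparms = (SEXP (*)(void)) R_GetCCallable("deSolve", "get_deSolve_gparms");
    gparms = get_gparms();
    if (LENGTH(gparms) < 10)
        error("parameter vector too short for crm model");
    if (REAL(gparms)[0] > MAX_CONSUMERS)
        error("crm model supports at most %d consumers", MAX_CONSUMERS);
}

void crm_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double *p = REAL(gparms);
    int nc = (int) p[0], nr = (int) p[1];
    double m = p[2], D = p[3];
    int essential = (int) p[4];
    double supply_on = p[5], mort_on = p[6];
    double *S  = p + 10;
    double *mu = p + 10 + 2 * nr;
    double *ks = mu + nc * nr;
    double *Q  = ks + nc * nr;
    double g[MAX_CONSUMERS];
    int i, j;

    /* negative excursions from the integrator are treated as zero */
    for (j = 0; j < nr; j++) {
        double R = y[nc + j] > 0 ? y[nc + j] : 0;
        ydot[nc + j] = supply_on * D * (S[j] - R);
    }

    if (!essential) {
        for (i = 0; i < nc; i++) g[i] = 0.0;
        for (j = 0; j < nr; j++) {
            double R = y[nc + j] > 0 ? y[nc + j] : 0;
            for (i = 0; i < nc; i++) {
                int k = i + nc * j;
                double mij = mu[k] * R / (ks[k] + R);
                double N = y[i] > 0 ? y[i] : 0;
                g[i] += mij;
                ydot[nc + j] -= Q[k] * mij * N;
            }
        }
    } else {
        /* Liebig's law: realised growth is the minimum Monod term, and
         * consumption of every resource is driven by that realised rate */
        for (i = 0; i < nc; i++) {
            double gmin = R_PosInf;
            for (j = 0; j < nr; j++) {
                int k = i + nc * j;
                double R = y[nc + j] > 0 ? y[nc + j] : 0;
                double mij = mu[k] * R / (ks[k] + R);
                if (mij < gmin) gmin = mij;
            }
            g[i] = gmin;
        }
        for (j = 0; j < nr; j++) {
            for (i = 0; i < nc; i++) {
                double N = y[i] > 0 ? y[i] : 0;
                ydot[nc + j] -= Q[i + nc * j] * g[i] * N;
            }
        }
    }

    for (i = 0; i < nc; i++) {
        double N = y[i] > 0 ? y[i] : 0;
        ydot[i] = N * (g[i] - mort_on * m);
    }
}

/* Pulse event: cell transfer (dilution by e^(-mT)) and resource input.
 * Serial-transfer dialect carries residual resources through the same
 * dilution as the cells; additive dialect tops resources up in place.
 * When cells are not diluted (continuous-mortality variant) resources are
 * topped up additively regardless of dialect. */
void crm_event(int *n, double *t, double *y)
{
    double *p = REAL(gparms);
    int nc = (int) p[0], nr = (int) p[1];
    double d = p[7];
    int additive = (int) p[8];
    int dilute_cells = (int) p[9];
    double *pulse = p + 10 + nr;
    int i, j;

    if (dilute_cells)
        for (i = 0; i < nc; i++) y[i] *= d;
    for (j = 0; j < nr; j++) {
        if (!additive && dilute_cells)
            y[nc + j] = d * y[nc + j] + pulse[j];
        else
            y[nc + j] += pulse[j];
    }
}

void R_init_pulseCR(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
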