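/* Mass-action right-hand sides for the nine-species TFPI / factor X
 * activation scheme, compiled for use with deSolve.
 *
 * Species order (fixed everywhere in the package):
 *   y[0] E      TF:VIIa
 *   y[1] S      factor X
 *   y[2] ES     TF:VIIa:X
 *   y[3] EP     TF:VIIa:Xa
 *   y[4] P      factor Xa
 *   y[5] I      TFPI
 *   y[6] PI     Xa:TFPI
 *   y[7] EPI    TF:VIIa:Xa:TFPI (transient)
 *   y[8] PIE    TF:VIIa:Xa:TFPI (tight)
 *
 * Static parameter vector (15): k+1, k-1, k+2, k+3, k-3, k+4, k-4,
 *   k+5, k-5, k+6, k-6, k+7, k-7, k+8, k-8.
 * Flow parameter vector (18): the 15 rates followed by k_flow, S_up, I_up.
 */

#include <R.h>

static double parms_static[15];
static double parms_flow[18];
static double parms_preinc[2];

void tfpi_init_static(void (*odeparms)(int *, double *))
{
    int n = 15;
    odeparms(&n, parms_static);
}

void tfpi_init_flow(void (*odeparms)(int *, double *))
{
    int n = 18;
    odeparms(&n, parms_flow);
}

void tfpi_init_preinc(void (*odeparms)(int *, double *))
{
    int n = 2;
    odeparms(&n, parms_preinc);
}

/* core mass-action terms shared by the static and flow systems */
static void mass_action(const double *k, const double *y, double *dy)
{
    /* yPI etc.: R.h defines a PI macro, so species locals carry a y prefix */
    double yE = y[0], yS = y[1], yES = y[2], yEP = y[3], yP = y[4];
    double yI = y[5], yPI = y[6], yEPI = y[7], yPIE = y[8];

    double kp1 = k[0],  km1 = k[1],  kp2 = k[2];
    double kp3 = k[3],  km3 = k[4];
    double kp4 = k[5],  km4 = k[6];
    double kp5 = k[7],  km5 = k[8];
    double kp6 = k[9],  km6 = k[10];
    double kp7 = k[11], km7 = k[12];
    double kp8 = k[13], km8 = k[14];

    double r1  = kp1 * yE * yS;    /* E + S -> E:S    */
    double rm1 = km1 * yES;        /* E:S -> E + S    */
    double r2  = kp2 * yES;        /* E:S -> E:P      */
    double r3  = kp3 * yE * yP;    /* E + P -> E:P    */
    double rm3 = km3 * yEP;        /* E:P -> E + P    */
    double r4  = kp4 * yP * yI;    /* P + I -> P:I    */
    double rm4 = km4 * yPI;        /* P:I -> P + I    */
    double r5  = kp5 * yE * yPI;   /* E + P:I -> P:I:E (removed multi-step) */
    double rm5 = km5 * yPIE;
    double r6  = kp6 * yEP * yI;   /* E:P + I -> E:P:I */
    double rm6 = km6 * yEPI;
    double r7  = kp7 * yEPI;       /* E:P:I -> P:I:E (conformational) */
    double rm7 = km7 * yPIE;
    double r8  = kp8 * yE * yPI;   /* E + P:I -> E:P:I */
    double rm8 = km8 * yEPI;

    dy[0] = -r1 + rm1 - r3 + rm3 - r5 + rm5 - r8 + rm8; /* E   */
    dy[1] = -r1 + rm1;                                  /* S   */
    dy[2] =  r1 - rm1 - r2;                             /* ES  */
    dy[3] =  r2 + r3 - rm3 - r6 + rm6;                  /* EP  */
    dy[4] = -r3 + rm3 - r4 + rm4;                       /* P   */
    dy[5] = -r4 + rm4 - r6 + rm6;                       /* I   */
    dy[6] =  r4 - rm4 - r5 + rm5 - r8 + rm8;            /* PI  */
    dy[7] =  r6 - rm6 - r7 + rm7 + r8 - rm8;            /* EPI */
    dy[8] =  r5 - rm5 + r7 - rm7;                       /* PIE */
}

void tfpi_derivs_static(int *neq, double *t, double *y, double *ydot,
                        double *yout, int *ip)
{
    mass_action(parms_static, y, ydot);
}

void tfpi_derivs_flow(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    double kflow = parms_flow[15];
    double Sup   = parms_flow[16];
    double Iup   = parms_flow[17];

    mass_action(parms_flow, y, ydot);

    /* flow touches only the solution-phase species; the enzyme complexes
     * are anchored at the injury site */
    ydot[1] += kflow * (Sup - y[1]); /* S  */
    ydot[4] -= kflow * y[4];         /* P  */
    ydot[5] += kflow * (Iup - y[5]); /* I  */
    ydot[6] -= kflow * y[6];         /* PI */
}

/* pre-incubation subsystem: P + I <-> P:I only; y = (P, I, PI) */
void tfpi_derivs_preinc(int *neq, double *t, double *y, double *ydot,
                        double *yout, int *ip)
{
    double kp4 = parms_preinc[0], km4 = parms_preinc[1];
    double r = kp4 * y[0] * y[1] - km4 * y[2];
    ydot[0] = -r;
    ydot[1] = -r;
    ydot[2] =  r;
}
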