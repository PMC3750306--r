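/* Mass-action right-hand sides of the apoptotic decision module,
 * in the deSolve compiled-model convention (initfunc + derivs).
 *
 * State order (molecules/cell):
 *   1 Bax_mRNA  2 Bax  3 BclxL  4 {Bax:BclxL}  5 {BclxL:Bad_u}
 *   6 Bad_u  7 Bad_p  8 {Bad_p:Scaffold}  9 Scaffold  10 Procasp  11 Casp
 *
 * Parameter order (see R/zzz-constants: .param_order):
 *   s1 s2 s3 s4 M d1 d2 d3 b1 b2 b3 u1 u2 u3 p1 q1 a1 a2 p53 aktp
 * p53 and aktp are the (phase-constant) input levels.
 */
#include <R.h>

static double parms[20];

#define P_s1   parms[0]
#define P_s2   parms[1]
#define P_s3   parms[2]
#define P_s4   parms[3]
#define P_M    parms[4]
#define P_d1   parms[5]
#define P_d2   parms[6]
#define P_d3   parms[7]
#define P_b1   parms[8]
#define P_b2   parms[9]
#define P_b3   parms[10]
#define P_u1   parms[11]
#define P_u2   parms[12]
#define P_u3   parms[13]
#define P_p1   parms[14]
#define P_q1   parms[15]
#define P_a1   parms[16]
#define P_a2   parms[17]
#define P_p53  parms[18]
#define P_aktp parms[19]

void bclgate_initmod(void (*odeparms)(int *, double *))
{
    int n = 20;
    odeparms(&n, parms);
}

/* shared Bcl-2 subsystem terms; fills ydot[0..8] */
static void bcl2_terms(double *y, double *ydot)
{
    double baxm = y[0], bax = y[1], bclxl = y[2], cbb = y[3], cbbadu = y[4];
    double badu = y[5], badp = y[6], cbs = y[7], scaf = y[8];

    double hill  = P_s1 + P_s2 * P_p53 * P_p53 / (P_M * P_M + P_p53 * P_p53);
    double v_b1  = P_b1 * bax * bclxl;      /* Bax + BclxL -> complex        */
    double v_u1  = P_u1 * cbb;              /* complex dissociation          */
    double v_b2  = P_b2 * bclxl * badu;     /* BclxL + Bad_u -> complex      */
    double v_u2  = P_u2 * cbbadu;
    double v_b3  = P_b3 * badp * scaf;      /* Bad_p + Scaffold -> complex   */
    double v_u3  = P_u3 * cbs;
    double v_pf  = P_p1 * P_aktp * badu;    /* phosphorylation, free Bad_u   */
    double v_pc  = P_p1 * P_aktp * cbbadu;  /* phosphorylation, complexed    */
    double v_qf  = P_q1 * badp;             /* dephosphorylation, free Bad_p */
    double v_qc  = P_q1 * cbs;              /* dephosphorylation, complexed  */

    ydot[0] = hill - P_d1 * baxm;
    ydot[1] = P_s4 * baxm + v_u1 - v_b1 - P_d2 * bax;
    ydot[2] = v_u2 + v_u1 + v_pc - v_b2 - v_b1 + P_d2 * cbb;
    ydot[3] = v_b1 - v_u1 - P_d2 * cbb;
    ydot[4] = v_b2 - v_u2 - v_pc;
    ydot[5] = v_u2 - v_b2 - v_pf + v_qf + v_qc;
    ydot[6] = v_u3 - v_b3 + v_pf + v_pc - v_qf;
    ydot[7] = v_b3 - v_u3 - v_qc;
    ydot[8] = v_u3 - v_b3 + v_qc;
}

/* full 11-species module */
void bclgate_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double bax = y[1], pro = y[9], casp = y[10];
    double v_act;

    bcl2_terms(y, ydot);
    v_act = (P_a1 * bax + P_a2 * casp * casp) * pro;
    ydot[9]  = P_s3 - v_act - P_d3 * pro;
    ydot[10] = v_act - P_d3 * casp;
}

/* caspase-independent 9-species Bcl-2 subsystem */
void bclgate_derivs9(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    bcl2_terms(y, ydot);
}
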