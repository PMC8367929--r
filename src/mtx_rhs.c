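/* Five-compartment minimal PBPK right-hand side for intravenous
 * methotrexate, compiled for deSolve's lsoda.
 *
 * States (mg): m_CS, m_RCS, m_HCS, m_ISF, m_ICF,
 *              cumulative renal excretion, cumulative hepatic elimination.
 * Units throughout: mg, mL, min.
 *
 * Parameters are passed per integration segment (infusion rate and the
 * individualized physiology are constant within a segment; the R side
 * restarts the solver at every dose/lab breakpoint).
 */
#include <R.h>

#define N_PARMS 23

static double parms[N_PARMS];

#define V_CS        parms[0]
#define V_RCS       parms[1]
#define V_HCS       parms[2]
#define V_ISF       parms[3]
#define V_ICF       parms[4]
#define Q_RCS       parms[5]   /* plasma flow CS <-> RCS, mL/min */
#define Q_HCS       parms[6]   /* plasma flow CS <-> HCS, mL/min */
#define Q_GFR       parms[7]   /* mL/min */
#define CL_HEP      parms[8]   /* mL/min */
#define MSEC_MAX    parms[9]   /* mg/min */
#define MREAB_MAX   parms[10]  /* mg/min */
#define K50_SEC     parms[11]  /* mg/mL (unbound) */
#define K50_REAB    parms[12]
#define FU_PLASMA   parms[13]
#define FU_ISF      parms[14]
#define FU_ICF      parms[15]
#define K_CS_ISF    parms[16]  /* permeability-surface area product, mL/min */
#define K_ISF_CS    parms[17]
#define MMAX_UPTAKE parms[18]  /* mg/min */
#define MMAX_EFFLUX parms[19]
#define K50_INFLUX  parms[20]  /* mg/mL (unbound) */
#define K50_EFFLUX  parms[21]
#define INF_RATE    parms[22]  /* mg/min */

void mtx_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

static double clamp0(double x) { return x > 0.0 ? x : 0.0; }

void mtx_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    /* tiny negative excursions within solver tolerance are treated as
       drug-free for rate evaluation */
    double m_cs  = clamp0(y[0]);
    double m_rcs = clamp0(y[1]);
    double m_hcs = clamp0(y[2]);
    double m_isf = clamp0(y[3]);
    double m_icf = clamp0(y[4]);

    double c_cs  = m_cs  / V_CS;
    double c_rcs = m_rcs / V_RCS;
    double c_hcs = m_hcs / V_HCS;
    double c_isf = m_isf / V_ISF;
    double c_icf = m_icf / V_ICF;

    /* renal excretion: free filtration of unbound drug plus saturable
       net tubular transport (secretion minus reabsorption) */
    double cu_rcs = FU_PLASMA * c_rcs;
    double renal = Q_GFR * cu_rcs
        + MSEC_MAX  * cu_rcs / (K50_SEC  + cu_rcs)
        - MREAB_MAX * cu_rcs / (K50_REAB + cu_rcs);

    /* hepatic elimination: linear clearance of unbound drug */
    double hepatic = CL_HEP * FU_PLASMA * c_hcs;

    /* capillary exchange (passive, unbound) */
    double cs_to_isf = K_CS_ISF * FU_PLASMA * c_cs;
    double isf_to_cs = K_ISF_CS * FU_ISF * c_isf;

    /* carrier-mediated cellular exchange (saturable, unbound) */
    double cu_isf = FU_ISF * c_isf;
    double cu_icf = FU_ICF * c_icf;
    double uptake = MMAX_UPTAKE * cu_isf / (K50_INFLUX + cu_isf);
    double efflux = MMAX_EFFLUX * cu_icf / (K50_EFFLUX + cu_icf);

    /* plasma flow exchange with renal / hepatic circulatory systems */
    double cs_rcs = Q_RCS * (c_cs - c_rcs);
    double cs_hcs = Q_HCS * (c_cs - c_hcs);

    ydot[0] = INF_RATE - cs_rcs - cs_hcs - cs_to_isf + isf_to_cs;
    ydot[1] = cs_rcs - renal;
    ydot[2] = cs_hcs - hepatic;
    ydot[3] = cs_to_isf - isf_to_cs - uptake + efflux;
    ydot[4] = uptake - efflux;
    ydot[5] = renal;
    ydot[6] = hepatic;
}
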