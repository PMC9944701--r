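/* Whole-body PBPK right-hand side for Tc99m-tetrofosmin, compiled for
 * deSolve.  States are amounts as percent of administered dose:
 *   y[0]  arterial blood        y[10] GI contents
 *   y[1]  venous blood          y[11] spleen
 *   y[2]  lung                  y[12] pancreas
 *   y[3]  heart vascular        y[13] kidney vascular
 *   y[4]  heart extravascular   y[14] kidney extravascular
 *   y[5]  brain vascular        y[15] urine (cumulative)
 *   y[6]  muscle                y[16] adipose
 *   y[7]  liver                 y[17] thyroid
 *   y[8]  gallbladder           y[18] other (remainder)
 *   y[9]  GI tissue             y[19] urinary bladder contents
 *
 * The bladder state receives the same renal flux as the cumulative urine
 * state; it exists so that dosimetry simulations can void it with events.
 * Mass balance holds over states 0..18 (urine included, bladder excluded).
 * With lambda > 0 every state additionally decays radioactively.
 */
#include <R.h>

#define NPAR 48
static double p[NPAR];

#define Q_LUNG     p[0]
#define Q_HEART    p[1]
#define Q_BRAIN    p[2]
#define Q_MUSCLE   p[3]
#define Q_LIVER    p[4]
#define Q_HEPATIC  p[5]
#define Q_GI       p[6]
#define Q_SPLEEN   p[7]
#define Q_PANCREAS p[8]
#define Q_KIDNEY   p[9]
#define Q_ADIPOSE  p[10]
#define Q_THYROID  p[11]
#define Q_OTHER    p[12]
#define V_ART      p[13]
#define V_VEN      p[14]
#define V_LUNG     p[15]
#define V_HEART_V  p[16]
#define V_HEART_EV p[17]
#define V_BRAIN_V  p[18]
#define V_MUSCLE   p[19]
#define V_LIVER    p[20]
#define V_GB       p[21]
#define V_GI       p[22]
#define V_SPLEEN   p[23]
#define V_PANCREAS p[24]
#define V_KIDNEY_V p[25]
#define V_KIDNEY_EV p[26]
#define V_ADIPOSE  p[27]
#define V_THYROID  p[28]
#define V_OTHER    p[29]
#define KP_LUNG    p[30]
#define KP_HEART   p[31]
#define KP_KIDNEY  p[32]
#define KP_LIVER   p[33]
#define KP_THYROID p[34]
#define KP_OTHER   p[35]
#define KP_MUSCLE  p[36]
#define KP_ADIPOSE p[37]
#define KP_GI      p[38]
#define KP_SPLEEN  p[39]
#define KP_PANCREAS p[40]
#define PS_HEART   p[41]
#define PS_KIDNEY  p[42]
#define CL_RENAL   p[43]
#define CL_LIVER   p[44]
#define K_GB       p[45]
#define RBP        p[46]
#define LAMBDA     p[47]

void pbpk_init(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, p);
}

void pbpk_deriv(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double cart = y[0] / V_ART;
    double cven = y[1] / V_VEN;
    double out_lung     = y[2] / (KP_LUNG * V_LUNG);
    double out_muscle   = RBP * y[6]  / (KP_MUSCLE   * V_MUSCLE);
    double out_liver    = RBP * y[7]  / (KP_LIVER    * V_LIVER);
    double out_gi       = RBP * y[9]  / (KP_GI       * V_GI);
    double out_spleen   = RBP * y[11] / (KP_SPLEEN   * V_SPLEEN);
    double out_pancreas = RBP * y[12] / (KP_PANCREAS * V_PANCREAS);
    double out_adipose  = RBP * y[16] / (KP_ADIPOSE  * V_ADIPOSE);
    double out_thyroid  = RBP * y[17] / (KP_THYROID  * V_THYROID);
    double out_other    = RBP * y[18] / (KP_OTHER    * V_OTHER);
    double c_heart_v  = y[3]  / V_HEART_V;
    double c_brain_v  = y[5]  / V_BRAIN_V;
    double c_kidney_v = y[13] / V_KIDNEY_V;
    double ps_heart_flux  = PS_HEART  * (RBP * y[4]  / (KP_HEART  * V_HEART_EV)  - c_heart_v);
    double ps_kidney_flux = PS_KIDNEY * (RBP * y[14] / (KP_KIDNEY * V_KIDNEY_EV) - c_kidney_v);
    double bile_flux  = CL_LIVER * y[7] / V_LIVER;
    double gb_flux    = K_GB * y[8] / V_GB;
    double renal_flux = CL_RENAL * c_kidney_v;

    ydot[0] = Q_LUNG * (out_lung - cart);                        /* arterial */
    ydot[1] = -Q_LUNG * cven + Q_MUSCLE * out_muscle             /* venous   */
        + Q_HEART * c_heart_v + Q_BRAIN * c_brain_v
        + Q_LIVER * out_liver + Q_THYROID * out_thyroid
        + Q_ADIPOSE * out_adipose + Q_KIDNEY * c_kidney_v
        + Q_OTHER * out_other;
    ydot[2] = Q_LUNG * (cven - out_lung);                        /* lung     */
    ydot[3] = Q_HEART * (cart - c_heart_v) + ps_heart_flux;      /* heart v  */
    ydot[4] = -ps_heart_flux;                                    /* heart ev */
    ydot[5] = Q_BRAIN * (cart - c_brain_v);                      /* brain v  */
    ydot[6] = Q_MUSCLE * (cart - out_muscle);                    /* muscle   */
    ydot[7] = -Q_LIVER * out_liver + Q_HEPATIC * cart            /* liver    */
        - bile_flux + Q_GI * out_gi + Q_PANCREAS * out_pancreas
        + Q_SPLEEN * out_spleen;
    ydot[8] = bile_flux - gb_flux;                               /* gallbladder */
    ydot[9] = Q_GI * (cart - out_gi);                            /* GI tissue   */
    ydot[10] = gb_flux;                                          /* GI contents */
    ydot[11] = Q_SPLEEN * (cart - out_spleen);                   /* spleen   */
    ydot[12] = Q_PANCREAS * (cart - out_pancreas);               /* pancreas */
    ydot[13] = Q_KIDNEY * (cart - c_kidney_v) - renal_flux       /* kidney v */
        + ps_kidney_flux;
    ydot[14] = -ps_kidney_flux;                                  /* kidney ev */
    ydot[15] = renal_flux;                                       /* urine     */
    ydot[16] = Q_ADIPOSE * (cart - out_adipose);                 /* adipose   */
    ydot[17] = Q_THYROID * (cart - out_thyroid);                 /* thyroid   */
    ydot[18] = Q_OTHER * (cart - out_other);                     /* other     */
    ydot[19] = renal_flux;                                       /* bladder   */

    if (LAMBDA > 0.0) {
        for (int i = 0; i < 20; i++) ydot[i] -= LAMBDA * y[i];
    }
}
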