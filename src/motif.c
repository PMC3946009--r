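/* Compiled right-hand sides for the phosphorylation-cascade feedback motifs.
 *
 * Species (state order): B, Bp, C, Cp, BpCp, D, Dp.
 * Mass-action reactions:
 *   1. B  -> Bp     rate k1 * u * B   (stimulus-driven phosphorylation)
 *   2. Bp -> B      rate k2 * Bp
 *   3. C  -> Cp     rate k3 * Bp * C  (Bp phosphorylates C)
 *   4. Cp -> C      rate k4 * Cp
 *   5. Bp + Cp -> BpCp   rate k5 * Bp * Cp  (complex formation)
 *   6. BpCp -> Bp + Cp   rate k6 * BpCp
 *   7. D  -> Dp     rate k7 * BpCp * D (complex-driven phosphorylation)
 *   8. Dp -> D      rate k8 * Dp
 *
 * Negative-feedback variants (parameter `variant`), inhibition factor
 * 1 / (1 + kf * X):
 *   1: Dp inhibits reaction 1       (feedback from cascade output; "true")
 *   2: Dp inhibits reaction 5       (output blocks complex formation)
 *   3: BpCp inhibits reaction 1     (complex feeds back on the input)
 *   4: Cp inhibits reaction 1       (feedback routed through Cp)
 *
 * Parameter vector (11): u, variant, k1..k8, kf.
 * Used through deSolve's compiled-model interface.
 */

#include <R.h>

static double parms[11];
#define P_u       parms[0]
#define P_variant parms[1]
#define P_k(i)    parms[1 + (i)] /* k1..k8 -> parms[2..9] */
#define P_kf      parms[10]

void motif_init(void (*odeparms)(int *, double *)) {
  int n = 11;
  odeparms(&n, parms);
}

void motif_derivs(int *neq, double *t, double *y, double *ydot, double *yout,
                  int *ip) {
  const double B = y[0], Bp = y[1], C = y[2], Cp = y[3], BpCp = y[4],
               D = y[5], Dp = y[6];
  const int variant = (int)(P_variant + 0.5);

  double f1 = 1.0, f5 = 1.0;
  switch (variant) {
  case 1: f1 = 1.0 / (1.0 + P_kf * Dp); break;
  case 2: f5 = 1.0 / (1.0 + P_kf * Dp); break;
  case 3: f1 = 1.0 / (1.0 + P_kf * BpCp); break;
  case 4: f1 = 1.0 / (1.0 + P_kf * Cp); break;
  default: break;
  }

  const double v1 = P_k(1) * P_u * B * f1;
  const double v2 = P_k(2) * Bp;
  const double v3 = P_k(3) * Bp * C;
  const double v4 = P_k(4) * Cp;
  const double v5 = P_k(5) * Bp * Cp * f5;
  const double v6 = P_k(6) * BpCp;
  const double v7 = P_k(7) * BpCp * D;
  const double v8 = P_k(8) * Dp;

  ydot[0] = -v1 + v2;              /* B    */
  ydot[1] = v1 - v2 - v5 + v6;     /* Bp   */
  ydot[2] = -v3 + v4;              /* C    */
  ydot[3] = v3 - v4 - v5 + v6;     /* Cp   */
  ydot[4] = v5 - v6;               /* BpCp */
  ydot[5] = -v7 + v8;              /* D    */
  ydot[6] = v7 - v8;               /* Dp   */
}
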