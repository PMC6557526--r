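/* Compiled right-hand sides for the DMT1 cycling models.
 *
 * State vector y (both models): P1..P6, FeIN.
 * The apical concentration is recovered from the within-challenge mass
 * balance FeOUT = FeOUT0 - (V_cb/V_a) * (FeIN - FeIN0), so it is not a
 * state and iron conservation is exact by construction.
 */

#include <R.h>

/* ---- binary switching-mechanism model -------------------------------- */

/* parms: k12 k23 k34 k41 k14 k45eff k54eff DMT1_E gamma vratio
 *        FeOUT0 FeIN0 alpha (root threshold) mode (0 endo, 1 exo)
 * k45eff/k54eff arrive already mode-resolved (one of them zero).     */
static double swp[14];

void switch_initmod(void (*odeparms)(int *, double *)) {
  int n = 14;
  odeparms(&n, swp);
}

void switch_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip) {
  double k12 = swp[0], k23 = swp[1], k34 = swp[2], k41 = swp[3],
         k14 = swp[4], k45 = swp[5], k54 = swp[6], dmt = swp[7],
         gamma = swp[8], vr = swp[9], feout0 = swp[10], fein0 = swp[11];
  double feout = feout0 - vr * (y[6] - fein0);
  double bind = k12 * y[0] * feout;
  double endo = k45 * feout * y[3];
  double exo = k54 * y[4];
  ydot[0] = -bind - k14 * y[0] + k41 * y[3];
  ydot[1] = bind - k23 * y[1];
  ydot[2] = k23 * y[1] - k34 * y[2];
  ydot[3] = k34 * y[2] + k14 * y[0] - k41 * y[3] + exo - endo;
  ydot[4] = endo - exo;
  ydot[5] = 0.0;
  ydot[6] = k34 * dmt * y[2] + gamma * k54 * dmt * y[4];
}

/* threshold function for the hysteretic mode flip */
void switch_root(int *neq, double *t, double *y, int *ng, double *gout,
                 double *out, int *ip) {
  double alpha = swp[12];
  int exo_mode = (int) swp[13];
  if (exo_mode)
    gout[0] = (y[0] + y[1] + y[2] + y[3]) - alpha;
  else
    gout[0] = y[4] - alpha;
}

/* ---- swinging-mechanism model ---------------------------------------- */

/* parms: k12 k23 k34 k41 k14 k45 k56 k64 DMT1_E gamma vratio
 *        FeOUT0 FeIN0 after_first (0/1) FeUP_prev chg_ratio clamp (0/1) */
static double sgp[17];

void swing_initmod(void (*odeparms)(int *, double *)) {
  int n = 17;
  odeparms(&n, sgp);
}

void swing_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip) {
  double k12 = sgp[0], k23 = sgp[1], k34 = sgp[2], k41 = sgp[3],
         k14 = sgp[4], k45 = sgp[5], k56 = sgp[6], k64 = sgp[7],
         dmt = sgp[8], gamma = sgp[9], vr = sgp[10], feout0 = sgp[11],
         fein0 = sgp[12];
  double fein = y[6];
  double feout = feout0 - vr * (fein - fein0);
  double rho = 1.0;
  if (sgp[13] != 0.0) { /* challenge 2 onwards: history-dependent damping */
    double f = fein > 1e-300 ? fein : 1e-300;
    rho = 1.0 - 2.8 * ((f - 1.67 * sgp[14]) / f) * sgp[15];
    if (sgp[16] != 0.0 && rho < 0.0) rho = 0.0;
  }
  double bind = k12 * y[0] * feout;
  double endo = rho * k45 * feout * y[3] * y[4];
  double conv = k56 * y[4] * y[5];
  double back = rho * k64 * y[5] * y[3];
  ydot[0] = -bind - k14 * y[0] + k41 * y[3];
  ydot[1] = bind - k23 * y[1];
  ydot[2] = k23 * y[1] - k34 * y[2];
  ydot[3] = k34 * y[2] + k14 * y[0] - k41 * y[3] + back - endo;
  ydot[4] = endo - conv;
  ydot[5] = conv - back;
  ydot[6] = k34 * dmt * y[2] + gamma * rho * k64 * dmt * y[5];
}
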