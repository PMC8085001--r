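// Shared declarations for the compiled ionic-model cores.
//
// All membrane potentials are in mV, time in ms, currents in pA/pF
// (densities), concentrations in mM. Positive externally injected current
// (i_in) depolarizes. Gate variables are advanced with Rush-Larsen
// exponential updates; membrane potential and concentrations with forward
// Euler. These are the conventions used throughout the package.

#ifndef OPTOGAP_MODELS_H
#define OPTOGAP_MODELS_H

#include <cmath>

namespace og {

// ---------------------------------------------------------------------------
// ten Tusscher et al. 2004 human ventricular myocyte, epicardial variant.
// State layout (17):
//   0 V, 1 m, 2 h, 3 j, 4 d, 5 f, 6 fCa, 7 r, 8 s, 9 xs, 10 xr1, 11 xr2,
//   12 g, 13 Cai, 14 CaSR, 15 Nai, 16 Ki
// ---------------------------------------------------------------------------
const int TNNP_N = 17;
const int TNNP_NGATE = 12;  // states 1..12
const double TNNP_CM_PF = 185.0;

void tnnp_init(double* y);
// dy: full derivative vector; ginf/gtau: steady state and time constant for
// the 12 gates (indices match state indices 1..12); gfreeze: Rush-Larsen
// freeze flag for the Ca-dependent gates (fCa, g).
// i_stim enters the K+ bookkeeping (electrode current is carried by K+ in the
// published formulation); i_other (junctional current) affects V only.
void tnnp_eval(const double* y, double i_stim, double i_other, double ina_frac,
               double* dy, double* ginf, double* gtau, bool* gfreeze);
// fix_nak: hold intracellular Na+/K+ fixed (quiescent-drift guard; Ca2+
// stays dynamic)
void tnnp_step(double* y, double dt, double i_stim, double i_other,
               double ina_frac, bool fix_nak);

// ---------------------------------------------------------------------------
// Paci et al. 2013 ventricular hiPSC-CM. Exposed in mV/ms/mM (the published
// model is in SI units; conversion happens inside the eval function).
// State layout (18):
//   0 V, 1 m, 2 h, 3 j, 4 d, 5 f1, 6 f2, 7 fCa, 8 Xr1, 9 Xr2, 10 Xs,
//   11 Xf, 12 q, 13 r, 14 g, 15 Cai, 16 CaSR, 17 Nai
// ---------------------------------------------------------------------------
const int PACI_N = 18;
const int PACI_NGATE = 14;  // states 1..14
const double PACI_CM_PF = 98.7109;

void paci_init(double* y);
void paci_eval(const double* y, double i_in, double ina_frac,
               double* dy, double* ginf, double* gtau, bool* gfreeze);
void paci_step(double* y, double dt, double i_in, double ina_frac);

// ---------------------------------------------------------------------------
// MacCannell et al. 2007 "active" ventricular fibroblast.
// State layout (3): 0 V, 1 r, 2 s
// Parameter vector layout (13):
//   0 Cm (pF), 1 gKv (nS/pF), 2 gK1, 3 gbNa, 4 INaKmax (pA/pF), 5 KmK (mM),
//   6 KmNa, 7 Vrev (mV), 8 B (mV), 9 Ko, 10 Ki, 11 Nao, 12 Nai
// ---------------------------------------------------------------------------
const int FIB_N = 3;

void fib_init(double* y);
void fib_eval(const double* y, const double* p, double i_in,
              double* dy, double* ginf, double* gtau);
void fib_step(double* y, const double* p, double dt, double i_in);

// ---------------------------------------------------------------------------
// Williams et al. 2013 four-state ChR2(H134R) photocycle.
// State layout (5): 0 O1, 1 O2, 2 C1, 3 C2, 4 p (light adaptation)
// Parameter vector layout (16):
//   0 gChR2 (nS/pF), 1 gamma, 2 rect_a, 3 rect_b, 4 rect_c (mV),
//   5 eps1, 6 eps2, 7 e12d (1/ms), 8 c1 (1/ms), 9 e21d, 10 c2,
//   11 Ic (mW/mm^2), 12 flux_factor (1/ms per mW/mm^2), 13 tau_p (ms),
//   14 theta_scale (per mW/mm^2), 15 variant (0 printed, 1 divided-by-Vm)
// ---------------------------------------------------------------------------
const int CHR2_N = 5;

void chr2_init(double* y);
double chr2_rect(double vm, const double* p);
double chr2_current(double o1, double o2, double vm, const double* p);
void chr2_eval(const double* y, const double* p, double vm, double irr,
               double* dy);
void chr2_step(double* y, const double* p, double dt, double vm, double irr);

}  // namespace og

#endif
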