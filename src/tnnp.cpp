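// ten Tusscher / Noble / Noble / Panfilov 2004 human ventricular myocyte,
// epicardial parameter set, transcribed from the published equations.

#include "models.h"

namespace og {

namespace {

const double Rgas = 8314.472;      // mJ/(mol K)
const double Temp = 310.0;         // K
const double Frdy = 96485.3415;    // C/mol
const double RTONF = Rgas * Temp / Frdy;  // 26.7138 mV

const double Ko = 5.4, Nao = 140.0, Cao = 2.0;  // mM

const double gNa = 14.838;
const double gK1 = 5.405;
const double gKr = 0.096;
const double gKs = 0.245;   // epicardial
const double gto = 0.294;   // epicardial
const double gCaL = 0.000175;
const double gbNa = 0.00029;
const double gbCa = 0.000592;
const double gpCa = 0.825;
const double KpCa = 0.0005;
const double gpK = 0.0146;
const double PNaK = 1.362;
const double KmK = 1.0, KmNa = 40.0;
const double kNaCa = 1000.0;
const double gam = 0.35, KmNai = 87.5, KmCa = 1.38, ksat = 0.1, alpha = 2.5;
const double Vmaxup = 0.000425, Kup = 0.00025;
const double arel = 0.016464, brel = 0.25, crel = 0.008232, Vleak = 8e-5;
const double Bufc = 0.15, Kbufc = 0.001, Bufsr = 10.0, Kbufsr = 0.3;
const double CAP = 0.185, Vc = 0.016404, Vsr = 0.001094;
const double pKNa = 0.03;

inline double sq(double x) { return x * x; }

}  // namespace

void tnnp_init(double* y) {
  y[0] = -86.2;    // V
  y[1] = 0.0;      // m
  y[2] = 0.75;     // h
  y[3] = 0.75;     // j
  y[4] = 0.0;      // d
  y[5] = 1.0;      // f
  y[6] = 1.0;      // fCa
  y[7] = 0.0;      // r
  y[8] = 1.0;      // s
  y[9] = 0.0;      // xs
  y[10] = 0.0;     // xr1
  y[11] = 1.0;     // xr2
  y[12] = 1.0;     // g
  y[13] = 0.0002;  // Cai
  y[14] = 0.2;     // CaSR
  y[15] = 11.6;    // Nai
  y[16] = 138.3;   // Ki
}

void tnnp_eval(const double* y, double i_stim, double i_other, double ina_frac,
               double* dy, double* ginf, double* gtau, bool* gfreeze) {
  const double V = y[0];
  const double m = y[1], h = y[2], j = y[3], d = y[4], f = y[5], fCa = y[6];
  const double r = y[7], s = y[8], xs = y[9], xr1 = y[10], xr2 = y[11];
  const double g = y[12];
  const double Cai = y[13], CaSR = y[14], Nai = y[15], Ki = y[16];

  const double EK = RTONF * std::log(Ko / Ki);
  const double ENa = RTONF * std::log(Nao / Nai);
  const double EKs = RTONF * std::log((Ko + pKNa * Nao) / (Ki + pKNa * Nai));
  const double ECa = 0.5 * RTONF * std::log(Cao / Cai);

  // Fast Na+
  const double INa = ina_frac * gNa * m * m * m * h * j * (V - ENa);

  // L-type Ca2+ (GHG flux form); limit at V -> 0
  const double vfort = V * Frdy / (Rgas * Temp);
  double ICaL;
  if (std::fabs(V) > 1e-6) {
    ICaL = gCaL * d * f * fCa * 4.0 * V * Frdy * Frdy / (Rgas * Temp) *
           (Cai * std::exp(2.0 * vfort) - 0.341 * Cao) /
           (std::exp(2.0 * vfort) - 1.0);
  } else {
    ICaL = gCaL * d * f * fCa * 2.0 * Frdy * (Cai - 0.341 * Cao);
  }

  // Inward rectifier
  const double aK1 = 0.1 / (1.0 + std::exp(0.06 * (V - EK - 200.0)));
  const double bK1 = (3.0 * std::exp(0.0002 * (V - EK + 100.0)) +
                      std::exp(0.1 * (V - EK - 10.0))) /
                     (1.0 + std::exp(-0.5 * (V - EK)));
  const double IK1 = gK1 * std::sqrt(Ko / 5.4) * aK1 / (aK1 + bK1) * (V - EK);

  const double Ito = gto * r * s * (V - EK);
  const double IKr = gKr * std::sqrt(Ko / 5.4) * xr1 * xr2 * (V - EK);
  const double IKs = gKs * xs * xs * (V - EKs);

  const double INaK = PNaK * Ko * Nai /
                      ((Ko + KmK) * (Nai + KmNa) *
                       (1.0 + 0.1245 * std::exp(-0.1 * vfort) +
                        0.0353 * std::exp(-vfort)));

  const double INaCa =
      kNaCa *
      (std::exp(gam * vfort) * Nai * Nai * Nai * Cao -
       std::exp((gam - 1.0) * vfort) * Nao * Nao * Nao * Cai * alpha) /
      ((KmNai * KmNai * KmNai + Nao * Nao * Nao) * (KmCa + Cao) *
       (1.0 + ksat * std::exp((gam - 1.0) * vfort)));

  const double IpCa = gpCa * Cai / (Cai + KpCa);
  const double IpK = gpK * (V - EK) / (1.0 + std::exp((25.0 - V) / 5.98));
  const double IbNa = gbNa * (V - ENa);
  const double IbCa = gbCa * (V - ECa);

  const double Itot = INa + ICaL + IK1 + Ito + IKr + IKs + INaK + INaCa +
                      IpCa + IpK + IbNa + IbCa;
  dy[0] = -Itot + i_stim + i_other;

  // --- gates ---
  // m
  {
    const double inf = 1.0 / sq(1.0 + std::exp((-56.86 - V) / 9.03));
    const double a = 1.0 / (1.0 + std::exp((-60.0 - V) / 5.0));
    const double b = 0.1 / (1.0 + std::exp((V + 35.0) / 5.0)) +
                     0.1 / (1.0 + std::exp((V - 50.0) / 200.0));
    ginf[0] = inf; gtau[0] = a * b;
  }
  // h
  {
    const double inf = 1.0 / sq(1.0 + std::exp((V + 71.55) / 7.43));
    double a, b;
    if (V >= -40.0) {
      a = 0.0;
      b = 0.77 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    } else {
      a = 0.057 * std::exp(-(V + 80.0) / 6.8);
      b = 2.7 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.3485 * V);
    }
    ginf[1] = inf; gtau[1] = 1.0 / (a + b);
  }
  // j
  {
    const double inf = ginf[1];
    double a, b;
    if (V >= -40.0) {
      a = 0.0;
      b = 0.6 * std::exp(0.057 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
    } else {
      a = (-2.5428e4 * std::exp(0.2444 * V) -
           6.948e-6 * std::exp(-0.04391 * V)) *
          (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
      b = 0.02424 * std::exp(-0.01052 * V) /
          (1.0 + std::exp(-0.1378 * (V + 40.14)));
    }
    ginf[2] = inf; gtau[2] = 1.0 / (a + b);
  }
  // d
  {
    const double inf = 1.0 / (1.0 + std::exp((-5.0 - V) / 7.5));
    const double a = 1.4 / (1.0 + std::exp((-35.0 - V) / 13.0)) + 0.25;
    const double b = 1.4 / (1.0 + std::exp((V + 5.0) / 5.0));
    const double c = 1.0 / (1.0 + std::exp((50.0 - V) / 20.0));
    ginf[3] = inf; gtau[3] = a * b + c;
  }
  // f
  {
    const double inf = 1.0 / (1.0 + std::exp((V + 20.0) / 7.0));
    const double tau = 1125.0 * std::exp(-sq(V + 27.0) / 240.0) + 80.0 +
                       165.0 / (1.0 + std::exp((25.0 - V) / 10.0));
    ginf[4] = inf; gtau[4] = tau;
  }
  // fCa (Ca-dependent; frozen when recovering while depolarized)
  {
    const double afca = 1.0 / (1.0 + std::pow(Cai / 0.000325, 8.0));
    const double bfca = 0.1 / (1.0 + std::exp((Cai - 0.0005) / 0.0001));
    const double cfca = 0.2 / (1.0 + std::exp((Cai - 0.00075) / 0.0008));
    const double inf = (afca + bfca + cfca + 0.23) / 1.46;
    ginf[5] = inf; gtau[5] = 2.0;
    gfreeze[0] = (inf > fCa) && (V > -60.0);
  }
  // r
  {
    ginf[6] = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));
    gtau[6] = 9.5 * std::exp(-sq(V + 40.0) / 1800.0) + 0.8;
  }
  // s (epicardial)
  {
    ginf[7] = 1.0 / (1.0 + std::exp((V + 20.0) / 5.0));
    gtau[7] = 85.0 * std::exp(-sq(V + 45.0) / 320.0) +
              5.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 3.0;
  }
  // xs
  {
    ginf[8] = 1.0 / (1.0 + std::exp((-5.0 - V) / 14.0));
    const double a = 1100.0 / std::sqrt(1.0 + std::exp((-10.0 - V) / 6.0));
    const double b = 1.0 / (1.0 + std::exp((V - 60.0) / 20.0));
    gtau[8] = a * b;
  }
  // xr1
  {
    ginf[9] = 1.0 / (1.0 + std::exp((-26.0 - V) / 7.0));
    const double a = 450.0 / (1.0 + std::exp((-45.0 - V) / 10.0));
    const double b = 6.0 / (1.0 + std::exp((V + 30.0) / 11.5));
    gtau[9] = a * b;
  }
  // xr2
  {
    ginf[10] = 1.0 / (1.0 + std::exp((V + 88.0) / 24.0));
    const double a = 3.0 / (1.0 + std::exp((-60.0 - V) / 20.0));
    const double b = 1.12 / (1.0 + std::exp((V - 60.0) / 20.0));
    gtau[10] = a * b;
  }
  // g (SR release gate; Ca-dependent with the same freeze rule as fCa)
  {
    double inf;
    if (Cai <= 0.00035)
      inf = 1.0 / (1.0 + std::pow(Cai / 0.00035, 6.0));
    else
      inf = 1.0 / (1.0 + std::pow(Cai / 0.00035, 16.0));
    ginf[11] = inf; gtau[11] = 2.0;
    gfreeze[1] = (inf > g) && (V > -60.0);
  }

  for (int k = 0; k < TNNP_NGATE; ++k)
    dy[1 + k] = (ginf[k] - y[1 + k]) / gtau[k];
  if (gfreeze[0]) dy[6] = 0.0;
  if (gfreeze[1]) dy[12] = 0.0;

  // --- intracellular ion dynamics ---
  const double Ileak = Vleak * (CaSR - Cai);
  const double Iup = Vmaxup / (1.0 + sq(Kup / Cai));
  const double Irel = (arel * CaSR * CaSR / (brel * brel + CaSR * CaSR) +
                       crel) * d * g;

  const double bufc_fac =
      1.0 / (1.0 + Bufc * Kbufc / sq(Cai + Kbufc));
  const double bufsr_fac =
      1.0 / (1.0 + Bufsr * Kbufsr / sq(CaSR + Kbufsr));

  dy[13] = bufc_fac *
           (-(ICaL + IbCa + IpCa - 2.0 * INaCa) * CAP / (2.0 * Vc * Frdy) +
            Ileak - Iup + Irel);
  dy[14] = bufsr_fac * (Vc / Vsr) * (Iup - Irel - Ileak);
  dy[15] = -(INa + IbNa + 3.0 * INaK + 3.0 * INaCa) * CAP / (Vc * Frdy);
  // electrode current assumed carried by K+ (published convention)
  dy[16] = -(IK1 + Ito + IKr + IKs - 2.0 * INaK + IpK - i_stim) * CAP /
           (Vc * Frdy);
}

void tnnp_step(double* y, double dt, double i_stim, double i_other,
               double ina_frac, bool fix_nak) {
  double dy[TNNP_N], ginf[TNNP_NGATE], gtau[TNNP_NGATE];
  bool gfreeze[2];
  tnnp_eval(y, i_stim, i_other, ina_frac, dy, ginf, gtau, gfreeze);

  y[0] += dt * dy[0];
  for (int k = 0; k < TNNP_NGATE; ++k) {
    const int i = 1 + k;
    if ((i == 6 && gfreeze[0]) || (i == 12 && gfreeze[1])) continue;
    y[i] = ginf[k] + (y[i] - ginf[k]) * std::exp(-dt / gtau[k]);
  }
  y[13] += dt * dy[13];
  y[14] += dt * dy[14];
  if (!fix_nak) {
    y[15] += dt * dy[15];
    y[16] += dt * dy[16];
  }
  // explicit-Euler guard: free Ca concentrations stay positive
  if (y[13] < 1e-9) y[13] = 1e-9;
  if (y[14] < 1e-9) y[14] = 1e-9;
}

}  // namespace og
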