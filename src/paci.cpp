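// Paci et al. 2013 ventricular hiPSC-derived cardiomyocyte model,
// transcribed from the published equations. The published model is in SI
// units (V, s); this translation exposes mV / ms / mM and converts
// internally (1 V/s == 1 mV/ms).

#include "models.h"

namespace og {

namespace {

const double Rgas = 8.314472;     // J/(mol K)
const double Temp = 310.0;        // K
const double Frdy = 96485.3415;   // C/mol

const double Cm = 9.87109e-11;    // F
const double Vc = 8800.0;         // um^3
const double Vsr = 583.73;        // um^3

const double Nao = 151.0, Ko = 5.4, Cao = 1.8;  // mM
const double Ki = 150.0;                        // mM, fixed

const double gNa = 3671.2302;     // S/F
const double gCaL = 8.635702e-5;  // m^3/(F s)
const double gKr = 29.8667;
const double gKs = 2.041;
const double gK1 = 28.1492;
const double gf = 30.10312;
const double Ef = -0.017;         // V
const double gto = 29.9038;
const double gbNa = 0.9;
const double gbCa = 0.69264;
const double gpCa = 0.4125;       // A/F
const double KpCa = 0.0005;
const double PNaK = 1.841424;
const double KmK = 1.0, KmNa = 40.0;
const double kNaCa = 4900.0;
const double gam = 0.35, KmNai = 87.5, KmCa = 1.38, ksat = 0.1;
const double alpha = 2.8571432;
const double Vmaxup = 0.56064;    // mM/s
const double Kup = 0.00025;
const double Vleak = 4.4444e-4;   // 1/s
const double arel = 16.464, brel = 0.25, crel = 8.232;
const double Bufc = 0.25, Kbufc = 0.001, Bufsr = 10.0, Kbufsr = 0.3;
const double pKNa = 0.03;
const double L0 = 0.025, Qfac = 2.3;

inline double sq(double x) { return x * x; }

}  // namespace

void paci_init(double* y) {
  // Published ventricular-variant initial conditions (V converted to mV).
  y[0] = -74.3340057623841;       // V (mV)
  y[1] = 0.102953468725004;       // m
  y[2] = 0.786926637881461;       // h
  y[3] = 0.253943221774722;       // j
  y[4] = 8.96088425225182e-5;     // d
  y[5] = 0.970411811263976;       // f1
  y[6] = 0.999965815466749;       // f2
  y[7] = 0.998925296531804;       // fCa
  y[8] = 0.00778547011240132;     // Xr1
  y[9] = 0.432162576531617;       // Xr2
  y[10] = 0.0322944866983666;     // Xs
  y[11] = 0.100615100568753;      // Xf
  y[12] = 0.839295925773219;      // q
  y[13] = 0.00573289893326379;    // r
  y[14] = 0.999999981028517;      // g
  y[15] = 0.0000802588983204;     // Cai (mM)
  y[16] = 0.273423475193100;      // CaSR (mM)
  y[17] = 10.9248496211574;       // Nai (mM)
}

void paci_eval(const double* y, double i_in, double ina_frac,
               double* dy, double* ginf, double* gtau, bool* gfreeze) {
  const double Vmv = y[0];
  const double V = Vmv * 1e-3;  // volts
  const double m = y[1], h = y[2], j = y[3], d = y[4], f1 = y[5], f2 = y[6];
  const double fCa = y[7], Xr1 = y[8], Xr2 = y[9], Xs = y[10], Xf = y[11];
  const double q = y[12], r = y[13], g = y[14];
  const double Cai = y[15], CaSR = y[16], Nai = y[17];

  const double RTF = Rgas * Temp / Frdy;  // volts
  const double EK = RTF * std::log(Ko / Ki);
  const double ENa = RTF * std::log(Nao / Nai);
  const double EKs = RTF * std::log((Ko + pKNa * Nao) / (Ki + pKNa * Nai));
  const double ECa = 0.5 * RTF * std::log(Cao / Cai);

  const double INa = ina_frac * gNa * m * m * m * h * j * (V - ENa);

  const double vfort = V * Frdy / (Rgas * Temp);
  double ICaL;
  if (std::fabs(V) > 1e-9) {
    ICaL = gCaL * 4.0 * V * Frdy * Frdy / (Rgas * Temp) *
           (Cai * std::exp(2.0 * vfort) - 0.341 * Cao) /
           (std::exp(2.0 * vfort) - 1.0) * d * f1 * f2 * fCa;
  } else {
    ICaL = gCaL * 2.0 * Frdy * (Cai - 0.341 * Cao) * d * f1 * f2 * fCa;
  }

  const double IKr = gKr * std::sqrt(Ko / 5.4) * Xr1 * Xr2 * (V - EK);
  const double IKs = gKs * Xs * Xs * (V - EKs) *
                     (1.0 + 0.6 / (1.0 + std::pow(3.8e-5 / Cai, 1.4)));

  const double vk = (Vmv - EK * 1000.0);
  const double aK1 = 3.91 / (1.0 + std::exp(0.5942 * (vk - 200.0)));
  const double bK1 = (-1.509 * std::exp(0.0002 * (vk + 100.0)) +
                      std::exp(0.5886 * (vk - 10.0))) /
                     (1.0 + std::exp(0.4547 * vk));
  const double IK1 = gK1 * std::sqrt(Ko / 5.4) * aK1 / (aK1 + bK1) * (V - EK);

  const double If = gf * Xf * (V - Ef);
  const double Ito = gto * q * r * (V - EK);

  const double INaK = PNaK * (Ko / (Ko + KmK)) * (Nai / (Nai + KmNa)) /
                      (1.0 + 0.1245 * std::exp(-0.1 * vfort) +
                       0.0353 * std::exp(-vfort));

  const double INaCa =
      kNaCa *
      (std::exp(gam * vfort) * Nai * Nai * Nai * Cao -
       std::exp((gam - 1.0) * vfort) * Nao * Nao * Nao * Cai * alpha) /
      ((KmNai * KmNai * KmNai + Nao * Nao * Nao) * (KmCa + Cao) *
       (1.0 + ksat * std::exp((gam - 1.0) * vfort)));

  const double IpCa = gpCa * Cai / (Cai + KpCa);
  const double IbNa = gbNa * (V - ENa);
  const double IbCa = gbCa * (V - ECa);

  const double Itot = INa + ICaL + IKr + IKs + IK1 + If + Ito + INaK +
                      INaCa + IpCa + IbNa + IbCa;
  // A/F == V/s; exposed as mV/ms
  dy[0] = -Itot + i_in;

  // --- gates (taus converted s -> ms) ---
  // m
  {
    const double inf =
        std::pow(1.0 / (1.0 + std::exp((-Vmv - 34.1) / 5.9)), 1.0 / 3.0);
    const double a = 1.0 / (1.0 + std::exp((-Vmv - 60.0) / 5.0));
    const double b = 0.1 / (1.0 + std::exp((Vmv + 35.0) / 5.0)) +
                     0.1 / (1.0 + std::exp((Vmv - 50.0) / 200.0));
    ginf[0] = inf; gtau[0] = a * b;  // ms
  }
  // h
  {
    const double inf = 1.0 / std::sqrt(1.0 + std::exp((Vmv + 72.1) / 5.7));
    const double a = (Vmv < -40.0) ? 0.057 * std::exp(-(Vmv + 80.0) / 6.8)
                                   : 0.0;
    const double b = (Vmv < -40.0)
                         ? 2.7 * std::exp(0.079 * Vmv) +
                               3.1e5 * std::exp(0.3485 * Vmv)
                         : 0.77 / (0.13 * (1.0 + std::exp(-(Vmv + 10.66) /
                                                          11.1)));
    double tau_s;
    if (Vmv < -40.0)
      tau_s = 1.5 / ((a + b) * 1000.0);
    else
      tau_s = 2.542 / 1000.0;
    ginf[1] = inf; gtau[1] = tau_s * 1000.0;
  }
  // j
  {
    const double inf = 1.0 / std::sqrt(1.0 + std::exp((Vmv + 72.1) / 5.7));
    double a, b;
    if (Vmv < -40.0) {
      a = (-25428.0 * std::exp(0.2444 * Vmv) -
           6.948e-6 * std::exp(-0.04391 * Vmv)) *
          (Vmv + 37.78) / (1.0 + std::exp(0.311 * (Vmv + 79.23)));
      b = 0.02424 * std::exp(-0.01052 * Vmv) /
          (1.0 + std::exp(-0.1378 * (Vmv + 40.14)));
    } else {
      a = 0.0;
      b = 0.6 * std::exp(0.057 * Vmv) /
          (1.0 + std::exp(-0.1 * (Vmv + 32.0)));
    }
    ginf[2] = inf; gtau[2] = 7.0 / ((a + b) * 1000.0) * 1000.0;
  }
  // d
  {
    const double inf = 1.0 / (1.0 + std::exp(-(Vmv + 9.1) / 7.0));
    const double a = 0.25 + 1.4 / (1.0 + std::exp((-Vmv - 35.0) / 13.0));
    const double b = 1.4 / (1.0 + std::exp((Vmv + 5.0) / 5.0));
    const double c = 1.0 / (1.0 + std::exp((-Vmv + 50.0) / 20.0));
    ginf[3] = inf; gtau[3] = a * b + c;  // ms
  }
  // f1 (Ca-dependent slowing of recovery on inactivation rebound)
  {
    const double inf = 1.0 / (1.0 + std::exp((Vmv + 26.0) / 3.0));
    double constf1 = 1.0;
    if (inf - f1 > 0.0) constf1 = 1.0 + 1433.0 * (Cai - 50.0e-6);
    const double tau =
        (20.0 + 1102.5 * std::exp(-sq(sq(Vmv + 27.0) / 15.0)) +
         200.0 / (1.0 + std::exp((13.0 - Vmv) / 10.0)) +
         180.0 / (1.0 + std::exp((30.0 + Vmv) / 10.0))) *
        constf1;
    ginf[4] = inf; gtau[4] = tau;  // ms
  }
  // f2
  {
    const double inf = 0.33 + 0.67 / (1.0 + std::exp((Vmv + 35.0) / 4.0));
    const double tau = 600.0 * std::exp(-sq(Vmv + 25.0) / 170.0) +
                       31.0 / (1.0 + std::exp((25.0 - Vmv) / 10.0)) +
                       16.0 / (1.0 + std::exp((30.0 + Vmv) / 10.0));
    ginf[5] = inf; gtau[5] = tau;  // ms
  }
  // fCa (gain-inactivation by Ca; frozen while depolarized and recovering)
  {
    const double afca = 1.0 / (1.0 + std::pow(Cai / 0.0006, 8.0));
    const double bfca = 0.1 / (1.0 + std::exp((Cai - 0.0009) / 0.0001));
    const double cfca = 0.3 / (1.0 + std::exp((Cai - 0.00075) / 0.0008));
    const double inf = (afca + bfca + cfca) / 1.3156;
    ginf[6] = inf; gtau[6] = 2.0;  // ms
    gfreeze[0] = (inf > fCa) && (Vmv > -60.0);
  }
  // Xr1
  {
    const double Vhalf =
        1000.0 * (-Rgas * Temp / (Frdy * Qfac) *
                      std::log(std::pow(1.0 + Cao / 2.6, 4.0) /
                               (L0 * std::pow(1.0 + Cao / 0.58, 4.0))) -
                  0.019);
    const double inf = 1.0 / (1.0 + std::exp((Vhalf - Vmv) / 4.9));
    const double a = 450.0 / (1.0 + std::exp((-45.0 - Vmv) / 10.0));
    const double b = 6.0 / (1.0 + std::exp((30.0 + Vmv) / 11.5));
    ginf[7] = inf; gtau[7] = a * b;  // ms
  }
  // Xr2
  {
    const double inf = 1.0 / (1.0 + std::exp((Vmv + 88.0) / 50.0));
    const double a = 3.0 / (1.0 + std::exp((-60.0 - Vmv) / 20.0));
    const double b = 1.12 / (1.0 + std::exp((-60.0 + Vmv) / 20.0));
    ginf[8] = inf; gtau[8] = a * b;  // ms
  }
  // Xs
  {
    const double inf = 1.0 / (1.0 + std::exp((-Vmv - 20.0) / 16.0));
    const double a = 1100.0 / std::sqrt(1.0 + std::exp((-10.0 - Vmv) / 6.0));
    const double b = 1.0 / (1.0 + std::exp((-60.0 + Vmv) / 20.0));
    ginf[9] = inf; gtau[9] = a * b;  // ms
  }
  // Xf (funny current activation)
  {
    const double inf = 1.0 / (1.0 + std::exp((Vmv + 77.85) / 5.0));
    const double tau = 1900.0 / (1.0 + std::exp((Vmv + 15.0) / 10.0));
    ginf[10] = inf; gtau[10] = tau;  // ms
  }
  // q
  {
    const double inf = 1.0 / (1.0 + std::exp((Vmv + 53.0) / 13.0));
    const double tau =
        6.06 + 39.102 / (0.57 * std::exp(-0.08 * (Vmv + 44.0)) +
                         0.065 * std::exp(0.1 * (Vmv + 45.93)));
    ginf[11] = inf; gtau[11] = tau;  // ms
  }
  // r
  {
    const double inf = 1.0 / (1.0 + std::exp(-(Vmv - 22.3) / 18.75));
    const double tau =
        2.75352 + 14.40516 / (1.037 * std::exp(0.09 * (Vmv + 30.61)) +
                              0.369 * std::exp(-0.12 * (Vmv + 23.84)));
    ginf[12] = inf; gtau[12] = tau;  // ms
  }
  // g (SR release gate)
  {
    double inf;
    if (Cai <= 0.00035)
      inf = 1.0 / (1.0 + std::pow(Cai / 0.00035, 6.0));
    else
      inf = 1.0 / (1.0 + std::pow(Cai / 0.00035, 16.0));
    ginf[13] = inf; gtau[13] = 2.0;  // ms
    gfreeze[1] = (inf > g) && (Vmv > -60.0);
  }

  for (int k = 0; k < PACI_NGATE; ++k)
    dy[1 + k] = (ginf[k] - y[1 + k]) / gtau[k];
  if (gfreeze[0]) dy[7] = 0.0;
  if (gfreeze[1]) dy[14] = 0.0;

  // --- Ca and Na dynamics (published rates are per second; exposed per ms)
  const double Irel = (crel + arel * CaSR * CaSR /
                                  (brel * brel + CaSR * CaSR)) *
                      d * g * 0.0411;                       // mM/s
  const double Iup = Vmaxup / (1.0 + sq(Kup) / sq(Cai));    // mM/s
  const double Ileak = (CaSR - Cai) * Vleak;                // mM/s

  const double bufc_fac = 1.0 / (1.0 + Bufc * Kbufc / sq(Cai + Kbufc));
  const double bufsr_fac = 1.0 / (1.0 + Bufsr * Kbufsr / sq(CaSR + Kbufsr));

  const double dCai_s =
      bufc_fac * (Ileak - Iup + Irel -
                  (ICaL + IbCa + IpCa - 2.0 * INaCa) * Cm /
                      (2.0 * Vc * Frdy * 1e-18));
  const double dCaSR_s =
      bufsr_fac * (Vc / Vsr) * (Iup - Irel - Ileak);
  const double dNai_s =
      -Cm * (INa + IbNa + 3.0 * INaK + 3.0 * INaCa) / (Frdy * Vc * 1e-18);

  dy[15] = dCai_s * 1e-3;
  dy[16] = dCaSR_s * 1e-3;
  dy[17] = dNai_s * 1e-3;
}

void paci_step(double* y, double dt, double i_in, double ina_frac) {
  double dy[PACI_N], ginf[PACI_NGATE], gtau[PACI_NGATE];
  bool gfreeze[2];
  paci_eval(y, i_in, ina_frac, dy, ginf, gtau, gfreeze);

  y[0] += dt * dy[0];
  for (int k = 0; k < PACI_NGATE; ++k) {
    const int i = 1 + k;
    if ((i == 7 && gfreeze[0]) || (i == 14 && gfreeze[1])) continue;
    y[i] = ginf[k] + (y[i] - ginf[k]) * std::exp(-dt / gtau[k]);
  }
  y[15] += dt * dy[15];
  y[16] += dt * dy[16];
  y[17] += dt * dy[17];
  // explicit-Euler guard: free Ca concentrations stay positive
  if (y[15] < 1e-9) y[15] = 1e-9;
  if (y[16] < 1e-9) y[16] = 1e-9;
}

}  // namespace og
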