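// MacCannell et al. 2007 active fibroblast and the Williams et al. 2013
// four-state ChR2(H134R) photocycle.

#include "models.h"

namespace og {

namespace {
const double RTONF = 8314.472 * 310.0 / 96485.3415;  // mV
inline double sq(double x) { return x * x; }
}

// ---------------------------------------------------------------------------
// Fibroblast
// ---------------------------------------------------------------------------

void fib_init(double* y) {
  y[0] = -49.6;  // V, near the published active-model resting potential
  y[1] = 0.0;    // r (Kv activation)
  y[2] = 1.0;    // s (Kv inactivation)
}

void fib_eval(const double* y, const double* p, double i_in,
              double* dy, double* ginf, double* gtau) {
  const double V = y[0], r = y[1], s = y[2];
  const double gKv = p[1], gK1 = p[2], gbNa = p[3], INaKmax = p[4];
  const double KmK = p[5], KmNa = p[6], Vrev = p[7], B = p[8];
  const double Ko = p[9], Ki = p[10], Nao = p[11], Nai = p[12];

  const double EK = RTONF * std::log(Ko / Ki);
  const double ENa = RTONF * std::log(Nao / Nai);

  const double IKv = gKv * r * s * (V - EK);

  const double aK1 = 0.1 / (1.0 + std::exp(0.06 * (V - EK - 200.0)));
  const double bK1 = (3.0 * std::exp(0.0002 * (V - EK + 100.0)) +
                      std::exp(0.1 * (V - EK - 10.0))) /
                     (1.0 + std::exp(-0.5 * (V - EK)));
  const double IK1 = gK1 * aK1 / (aK1 + bK1) * (V - EK);

  const double nafac = std::pow(Nai, 1.5) /
                       (std::pow(Nai, 1.5) + std::pow(KmNa, 1.5));
  const double INaK = INaKmax * (Ko / (Ko + KmK)) * nafac *
                      (V - Vrev) / (V - B);

  const double IbNa = gbNa * (V - ENa);

  dy[0] = -(IKv + IK1 + INaK + IbNa) + i_in;

  ginf[0] = 1.0 / (1.0 + std::exp(-(V + 20.0) / 11.0));
  gtau[0] = 20.3 + 138.0 * std::exp(-sq((V + 20.0) / 25.9));
  ginf[1] = 1.0 / (1.0 + std::exp((V + 23.0) / 7.0));
  gtau[1] = 1574.0 + 5268.0 * std::exp(-sq((V + 23.0) / 22.7));

  dy[1] = (ginf[0] - r) / gtau[0];
  dy[2] = (ginf[1] - s) / gtau[1];
}

void fib_step(double* y, const double* p, double dt, double i_in) {
  double dy[FIB_N], ginf[2], gtau[2];
  fib_eval(y, p, i_in, dy, ginf, gtau);
  y[0] += dt * dy[0];
  y[1] = ginf[0] + (y[1] - ginf[0]) * std::exp(-dt / gtau[0]);
  y[2] = ginf[1] + (y[2] - ginf[1]) * std::exp(-dt / gtau[1]);
}

// ---------------------------------------------------------------------------
// ChR2 photocycle
// ---------------------------------------------------------------------------

void chr2_init(double* y) {
  y[0] = 0.0;  // O1
  y[1] = 0.0;  // O2
  y[2] = 1.0;  // C1 (dark-adapted closed)
  y[3] = 0.0;  // C2
  y[4] = 0.0;  // p
}

double chr2_rect(double vm, const double* p) {
  // printed form: a - b*exp(-Vm/c)
  return p[2] - p[3] * std::exp(-vm / p[4]);
}

double chr2_current(double o1, double o2, double vm, const double* p) {
  const double occ = o1 + p[1] * o2;
  if (p[15] < 0.5) {
    return p[0] * occ * chr2_rect(vm, p);
  }
  // divided-by-Vm variant of the rectification factor, with explicit zero
  // reversal potential; numerically identical to the printed form except at
  // the removable singularity Vm -> 0.
  if (std::fabs(vm) < 1e-6) return p[0] * occ * chr2_rect(vm, p);
  return p[0] * occ * (chr2_rect(vm, p) / vm) * (vm - 0.0);
}

namespace {
// light-dependent rates; irr in mW/mm^2
inline void chr2_rates(const double* p, double vm, double irr,
                       double& k1, double& k2, double& Gd1, double& Gd2,
                       double& Gr, double& e12, double& e21, double& S0,
                       double pada) {
  const double eps1 = p[5], eps2 = p[6];
  const double e12d = p[7], c1 = p[8], e21d = p[9], c2 = p[10];
  const double Ic = p[11], flux = p[12], thsc = p[14];

  const double F = flux * irr;             // effective activation flux, 1/ms
  k1 = eps1 * F * pada;
  k2 = eps2 * F * pada;
  Gd1 = 0.075 + 0.043 * std::tanh(-(vm + 20.0) / 20.0);
  Gd2 = 0.05;
  Gr = 4.34587e-5 * std::exp(-0.0211539274 * vm);
  const double lf = std::log(1.0 + irr / Ic);
  e12 = e12d + c1 * lf;
  e21 = e21d + c2 * lf;
  S0 = 0.5 * (1.0 + std::tanh(120.0 * (thsc * irr - 0.1)));
}
}  // namespace

void chr2_eval(const double* y, const double* p, double vm, double irr,
               double* dy) {
  const double O1 = y[0], O2 = y[1], C1 = y[2], C2 = y[3], pada = y[4];
  double k1, k2, Gd1, Gd2, Gr, e12, e21, S0;
  chr2_rates(p, vm, irr, k1, k2, Gd1, Gd2, Gr, e12, e21, S0, pada);

  dy[0] = k1 * C1 - (Gd1 + e12) * O1 + e21 * O2;
  dy[1] = k2 * C2 + e12 * O1 - (Gd2 + e21) * O2;
  dy[2] = Gd1 * O1 + Gr * C2 - k1 * C1;
  dy[3] = Gd2 * O2 - (k2 + Gr) * C2;
  dy[4] = (S0 - pada) / p[13];
}

void chr2_step(double* y, const double* p, double dt, double vm, double irr) {
  double k1, k2, Gd1, Gd2, Gr, e12, e21, S0;
  chr2_rates(p, vm, irr, k1, k2, Gd1, Gd2, Gr, e12, e21, S0, y[4]);

  // Explicit Euler on the conservative 4-state system, sub-stepped so the
  // fastest transition rate (k1 grows with irradiance) stays well inside
  // the stability region. Occupancy conservation is exact because the
  // derivatives sum to zero.
  const double rmax = std::max(std::max(k1, k2),
                               std::max(Gd1 + e12, Gd2 + e21));
  int nsub = 1 + static_cast<int>(dt * rmax / 0.2);
  const double h = dt / nsub;
  for (int s = 0; s < nsub; ++s) {
    const double O1 = y[0], O2 = y[1], C1 = y[2], C2 = y[3];
    const double dO1 = k1 * C1 - (Gd1 + e12) * O1 + e21 * O2;
    const double dO2 = k2 * C2 + e12 * O1 - (Gd2 + e21) * O2;
    const double dC1 = Gd1 * O1 + Gr * C2 - k1 * C1;
    const double dC2 = Gd2 * O2 - (k2 + Gr) * C2;
    y[0] += h * dO1;
    y[1] += h * dO2;
    y[2] += h * dC1;
    y[3] += h * dC2;
  }
  for (int c = 0; c < 4; ++c) {
    if (y[c] < 0.0) y[c] = 0.0;
    if (y[c] > 1.0) y[c] = 1.0;
  }
  y[4] = S0 + (y[4] - S0) * std::exp(-dt / p[13]);
}

}  // namespace og
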