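// Rcpp interface: exported right-hand sides, single-cell runner, and the
// tandem-cell-unit (TCU) integrator.

#include <Rcpp.h>
#include "models.h"

using namespace Rcpp;
using namespace og;

namespace {

// is a pulsed stimulus on at time t?
inline bool pulse_on(double t, double dur, double period, int n,
                     double onset) {
  if (t < onset || dur <= 0.0) return false;
  const double tt = t - onset;
  if (period <= 0.0) return n >= 1 && tt < dur;
  const int k = static_cast<int>(tt / period);
  if (k >= n) return false;
  return (tt - k * period) < dur;
}

}  // namespace

// [[Rcpp::export]]
NumericVector tnnp_init_cpp() {
  NumericVector y(TNNP_N);
  tnnp_init(y.begin());
  return y;
}

// [[Rcpp::export]]
NumericVector paci_init_cpp() {
  NumericVector y(PACI_N);
  paci_init(y.begin());
  return y;
}

// [[Rcpp::export]]
NumericVector fib_init_cpp() {
  NumericVector y(FIB_N);
  fib_init(y.begin());
  return y;
}

// [[Rcpp::export]]
NumericVector chr2_init_cpp() {
  NumericVector y(CHR2_N);
  chr2_init(y.begin());
  return y;
}

// [[Rcpp::export]]
NumericVector tnnp_rhs_cpp(NumericVector y, double i_stim, double i_other,
                           double ina_frac) {
  NumericVector dy(TNNP_N);
  double ginf[TNNP_NGATE], gtau[TNNP_NGATE];
  bool gfreeze[2];
  tnnp_eval(y.begin(), i_stim, i_other, ina_frac, dy.begin(), ginf, gtau,
            gfreeze);
  return dy;
}

// [[Rcpp::export]]
NumericVector paci_rhs_cpp(NumericVector y, double i_in, double ina_frac) {
  NumericVector dy(PACI_N);
  double ginf[PACI_NGATE], gtau[PACI_NGATE];
  bool gfreeze[2];
  paci_eval(y.begin(), i_in, ina_frac, dy.begin(), ginf, gtau, gfreeze);
  return dy;
}

// [[Rcpp::export]]
NumericVector fib_rhs_cpp(NumericVector y, NumericVector pars, double i_in) {
  NumericVector dy(FIB_N);
  double ginf[2], gtau[2];
  fib_eval(y.begin(), pars.begin(), i_in, dy.begin(), ginf, gtau);
  return dy;
}

// [[Rcpp::export]]
NumericVector chr2_rhs_cpp(NumericVector y, NumericVector pars, double vm,
                           double irr) {
  NumericVector dy(CHR2_N);
  chr2_eval(y.begin(), pars.begin(), vm, irr, dy.begin());
  return dy;
}

// [[Rcpp::export]]
double chr2_rect_cpp(double vm, NumericVector pars) {
  return chr2_rect(vm, pars.begin());
}

// [[Rcpp::export]]
double chr2_current_cpp(double o1, double o2, double vm, NumericVector pars) {
  return chr2_current(o1, o2, vm, pars.begin());
}

// Integrate the photocycle alone at clamped membrane potential / irradiance.
// [[Rcpp::export]]
NumericVector chr2_run_cpp(NumericVector y, NumericVector pars, double vm,
                           double irr, double duration, double dt) {
  NumericVector out = clone(y);
  const int nstep = static_cast<int>(std::lround(duration / dt));
  for (int i = 0; i < nstep; ++i)
    chr2_step(out.begin(), pars.begin(), dt, vm, irr);
  return out;
}

// ---------------------------------------------------------------------------
// Single-cell runner. type: 1 = host ventricular CM (ten Tusscher epi),
// 2 = hiPSC-CM (Paci ventricular), 3 = fibroblast (MacCannell).
// A ChR2 block (5 trailing state entries) may be attached to any cell type.
// el / opt stimulus vectors: (amplitude, duration, period, n, onset);
// electrical amplitude in pA/pF, optical in mW/mm^2.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cell_run_cpp(int type, NumericVector y0, NumericVector fib_pars,
                  NumericVector chr2_pars, bool chr2_on, double ina_frac,
                  bool fix_nak, NumericVector el, NumericVector opt,
                  double duration, double dt, double record_dt) {
  const int nbase = (type == 1) ? TNNP_N : (type == 2) ? PACI_N : FIB_N;
  const int ntot = nbase + (chr2_on ? CHR2_N : 0);
  if (y0.size() != ntot) stop("state vector has wrong length");

  std::vector<double> y(y0.begin(), y0.end());
  const int nstep = static_cast<int>(std::lround(duration / dt));
  const int stride = std::max(1, static_cast<int>(std::lround(record_dt / dt)));
  const int nrec = nstep / stride + 1;

  NumericVector t_out(nrec), v_out(nrec), ichr2_out(nrec);
  int irec = 0;

  for (int i = 0; i <= nstep; ++i) {
    const double t = i * dt;
    const double vm = y[0];
    const double irr =
        (chr2_on && pulse_on(t, opt[1], opt[2], static_cast<int>(opt[3]),
                             opt[4]))
            ? opt[0] : 0.0;
    const double istim =
        pulse_on(t, el[1], el[2], static_cast<int>(el[3]), el[4]) ? el[0]
                                                                  : 0.0;
    double ichr2 = 0.0;
    if (chr2_on)
      ichr2 = chr2_current(y[nbase], y[nbase + 1], vm, chr2_pars.begin());

    if (i % stride == 0 && irec < nrec) {
      t_out[irec] = t;
      v_out[irec] = vm;
      ichr2_out[irec] = ichr2;
      ++irec;
    }
    if (i == nstep) break;

    if (type == 1) {
      tnnp_step(y.data(), dt, istim, -ichr2, ina_frac, fix_nak);
    } else if (type == 2) {
      paci_step(y.data(), dt, istim - ichr2, ina_frac);
    } else {
      fib_step(y.data(), fib_pars.begin(), dt, istim - ichr2);
    }
    if (chr2_on) chr2_step(y.data() + nbase, chr2_pars.begin(), dt, vm, irr);
  }

  return List::create(_["time"] = t_out, _["v"] = v_out,
                      _["i_chr2"] = ichr2_out,
                      _["final"] = NumericVector(y.begin(), y.end()));
}

// ---------------------------------------------------------------------------
// Tandem cell unit: one host CM coupled to n mutually uncoupled donors via
// identical ohmic junctions G_gj (nS). Light drives donor ChR2 only;
// electrical stimulus drives the host.
// host_type: 1 = ten Tusscher epi. donor_type: 2 = Paci hiPSC-CM,
// 3 = MacCannell fibroblast.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List tcu_run_cpp(int host_type, NumericVector host_y0, int donor_type,
                 NumericMatrix donor_y0, bool chr2_on, NumericVector fib_pars,
                 NumericVector chr2_pars, double host_ina, double donor_ina,
                 double g_gj, double host_cm, bool host_fix_nak,
                 NumericVector opt, NumericVector el, double duration,
                 double dt, double record_dt) {
  if (host_type != 1) stop("unknown host type");
  if (donor_type != 2 && donor_type != 3) stop("unknown donor type");

  const int ndon = donor_y0.nrow();
  const int nbase = (donor_type == 2) ? PACI_N : FIB_N;
  const int nd = nbase + (chr2_on ? CHR2_N : 0);
  if (donor_y0.ncol() != nd) stop("donor state matrix has wrong width");
  if (host_y0.size() != TNNP_N) stop("host state vector has wrong length");

  const double donor_cm = (donor_type == 2) ? PACI_CM_PF : fib_pars[0];

  std::vector<double> yh(host_y0.begin(), host_y0.end());
  std::vector<double> yd(donor_y0.begin(), donor_y0.end());  // column-major

  const int nstep = static_cast<int>(std::lround(duration / dt));
  const int stride = std::max(1, static_cast<int>(std::lround(record_dt / dt)));
  const int nrec = nstep / stride + 1;

  NumericVector t_out(nrec), vh_out(nrec), igj_out(nrec), ichr2_out(nrec),
      irr_out(nrec);
  NumericMatrix vd_out(nrec, ndon);
  int irec = 0;

  std::vector<double> igj(ndon), ichr2(ndon);

  for (int i = 0; i <= nstep; ++i) {
    const double t = i * dt;
    const double vh = yh[0];
    const double irr =
        (chr2_on && pulse_on(t, opt[1], opt[2], static_cast<int>(opt[3]),
                             opt[4]))
            ? opt[0] : 0.0;
    const double istim =
        pulse_on(t, el[1], el[2], static_cast<int>(el[3]), el[4]) ? el[0]
                                                                  : 0.0;

    double igj_sum = 0.0, ichr2_sum = 0.0;
    for (int k = 0; k < ndon; ++k) {
      const double vd = yd[k];  // column 0 row k
      igj[k] = g_gj * (vd - vh);  // pA, positive into the host
      igj_sum += igj[k];
      if (chr2_on) {
        ichr2[k] = chr2_current(yd[k + ndon * nbase],
                                yd[k + ndon * (nbase + 1)], vd,
                                chr2_pars.begin());
        ichr2_sum += ichr2[k];
      } else {
        ichr2[k] = 0.0;
      }
    }

    if (i % stride == 0 && irec < nrec) {
      t_out[irec] = t;
      vh_out[irec] = vh;
      igj_out[irec] = igj_sum;
      ichr2_out[irec] = ichr2_sum / ndon;
      irr_out[irec] = irr;
      for (int k = 0; k < ndon; ++k) vd_out(irec, k) = yd[k];
      ++irec;
    }
    if (i == nstep) break;

    // advance donors
    for (int k = 0; k < ndon; ++k) {
      double ydk[PACI_N + CHR2_N];
      for (int c = 0; c < nd; ++c) ydk[c] = yd[k + ndon * c];
      const double vd_old = ydk[0];
      const double i_in = -igj[k] / donor_cm - ichr2[k];
      if (donor_type == 2)
        paci_step(ydk, dt, i_in, donor_ina);
      else
        fib_step(ydk, fib_pars.begin(), dt, i_in);
      if (chr2_on)
        chr2_step(ydk + nbase, chr2_pars.begin(), dt, vd_old, irr);
      for (int c = 0; c < nd; ++c) yd[k + ndon * c] = ydk[c];
    }

    // advance host
    tnnp_step(yh.data(), dt, istim, igj_sum / host_cm, host_ina,
              host_fix_nak);
  }

  NumericMatrix donor_final(ndon, nd);
  std::copy(yd.begin(), yd.end(), donor_final.begin());
  return List::create(
      _["time"] = t_out, _["v_host"] = vh_out, _["v_donor"] = vd_out,
      _["i_gj"] = igj_out, _["i_chr2"] = ichr2_out, _["irradiance"] = irr_out,
      _["host_final"] = NumericVector(yh.begin(), yh.end()),
      _["donor_final"] = donor_final);
}
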