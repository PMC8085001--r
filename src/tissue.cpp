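// Reduced-scale 2D monodomain sheet with stochastic donor-cell placement.
//
// Every node carries a host ventricular CM (ten Tusscher epi). Occupied
// nodes additionally carry ONE donor fibroblast+ChR2 ODE copy whose
// junctional current into the host is multiplied by n_FB: identical,
// mutually uncoupled donors attached to the same host node see the same
// potentials and light, so their trajectories coincide exactly and a single
// representative suffices.
//
// Operator splitting: reaction step per node (Rush-Larsen / Euler), then
// explicit 5-point diffusion with no-flux boundaries.

#include <Rcpp.h>
#include "models.h"

using namespace Rcpp;
using namespace og;

namespace {
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

// occ_nodes: 0-based node indices carrying donor TCUs (node = iy*nx + ix).
// rel_irr: relative irradiance (exp(-depth/delta)) at each occupied node;
//          the run's surface amplitude E0 scales it.
// pace_nodes: nodes receiving the electrical preamble stimulus.
// act_from: activation times recorded for the first upward 0 mV crossing at
//           t >= act_from (ms).
// probe_nodes: nodes whose host Vm is recorded at record_dt resolution.
// [[Rcpp::export]]
List tissue_run_cpp(int nx, int ny, double h, double d_diff,
                    NumericMatrix host_y0, NumericMatrix donor_y0,
                    IntegerVector occ_nodes, double n_fb,
                    NumericVector fib_pars, NumericVector chr2_pars,
                    double g_gj, double host_ina, double host_cm,
                    bool host_fix_nak, NumericVector rel_irr,
                    double e0, double opt_onset, double opt_dur,
                    IntegerVector pace_nodes, NumericVector pace,
                    double duration, double dt, double record_dt,
                    double act_from, IntegerVector probe_nodes) {
  const int nnode = nx * ny;
  if (host_y0.nrow() != nnode || host_y0.ncol() != TNNP_N)
    stop("host state matrix must be nnode x 17");
  const int nocc = occ_nodes.size();
  const int nd = FIB_N + CHR2_N;
  if (nocc > 0 && (donor_y0.nrow() != nocc || donor_y0.ncol() != nd))
    stop("donor state matrix must be n_occupied x 8");

  const double donor_cm = fib_pars[0];

  std::vector<double> yh(host_y0.begin(), host_y0.end());  // column-major
  std::vector<double> yd(donor_y0.begin(), donor_y0.end());
  std::vector<double> vnew(nnode);

  std::vector<int> occ_at(nnode, -1);
  for (int k = 0; k < nocc; ++k) occ_at[occ_nodes[k]] = k;
  std::vector<char> paced(nnode, 0);
  for (int k = 0; k < pace_nodes.size(); ++k) paced[pace_nodes[k]] = 1;

  const int nstep = static_cast<int>(std::lround(duration / dt));
  const int stride = std::max(1, static_cast<int>(std::lround(record_dt / dt)));
  const int nrec = nstep / stride + 1;
  const int nprobe = probe_nodes.size();

  NumericVector t_out(nrec);
  NumericMatrix v_probe(nrec, nprobe);
  NumericVector act(nnode, NA_REAL);
  int irec = 0;
  bool unstable = false;
  double t_unstable = NA_REAL;

  const double alpha = d_diff * dt / (h * h);

  for (int i = 0; i <= nstep; ++i) {
    const double t = i * dt;

    if (i % stride == 0 && irec < nrec) {
      t_out[irec] = t;
      for (int k = 0; k < nprobe; ++k)
        v_probe(irec, k) = yh[probe_nodes[k]];
      ++irec;
    }
    if (i == nstep || unstable) break;

    const bool light_on = pulse_on(t, opt_dur, 0.0, 1, opt_onset);
    const double istim_amp =
        pulse_on(t, pace[1], pace[2], static_cast<int>(pace[3]), pace[4])
            ? pace[0] : 0.0;

    // reaction step
    std::vector<double> vold(yh.begin(), yh.begin() + nnode);
    for (int nidx = 0; nidx < nnode; ++nidx) {
      const double vh = yh[nidx];
      double i_other = 0.0;
      const int k = occ_at[nidx];
      double ydk[FIB_N + CHR2_N];
      double igj = 0.0;
      if (k >= 0) {
        for (int c = 0; c < nd; ++c) ydk[c] = yd[k + nocc * c];
        const double vd = ydk[0];
        igj = g_gj * (vd - vh);  // pA per donor, positive into host
        i_other += n_fb * igj / host_cm;
        const double irr = light_on ? e0 * rel_irr[k] : 0.0;
        const double ichr2 =
            chr2_current(ydk[FIB_N], ydk[FIB_N + 1], vd, chr2_pars.begin());
        fib_step(ydk, fib_pars.begin(), dt, -igj / donor_cm - ichr2);
        chr2_step(ydk + FIB_N, chr2_pars.begin(), dt, vd, irr);
        for (int c = 0; c < nd; ++c) yd[k + nocc * c] = ydk[c];
      }
      const double istim = paced[nidx] ? istim_amp : 0.0;
      // strided single-node view of the column-major host state
      double yloc[TNNP_N];
      for (int c = 0; c < TNNP_N; ++c) yloc[c] = yh[nidx + nnode * c];
      tnnp_step(yloc, dt, istim, i_other, host_ina, host_fix_nak);
      for (int c = 0; c < TNNP_N; ++c) yh[nidx + nnode * c] = yloc[c];
    }

    // diffusion step (host Vm only), no-flux boundaries
    for (int iy = 0; iy < ny; ++iy) {
      for (int ix = 0; ix < nx; ++ix) {
        const int nidx = iy * nx + ix;
        const double v = yh[nidx];
        const double vl = yh[iy * nx + (ix > 0 ? ix - 1 : ix + 1)];
        const double vr = yh[iy * nx + (ix < nx - 1 ? ix + 1 : ix - 1)];
        const double vdn = yh[(iy > 0 ? iy - 1 : iy + 1) * nx + ix];
        const double vup = yh[(iy < ny - 1 ? iy + 1 : iy - 1) * nx + ix];
        vnew[nidx] = v + alpha * (vl + vr + vdn + vup - 4.0 * v);
      }
    }
    const double tnext = t + dt;
    for (int nidx = 0; nidx < nnode; ++nidx) {
      yh[nidx] = vnew[nidx];
      if (tnext >= act_from && NumericVector::is_na(act[nidx]) &&
          vold[nidx] <= 0.0 && vnew[nidx] > 0.0)
        act[nidx] = tnext;
      if (vnew[nidx] < -150.0 || vnew[nidx] > 150.0 ||
          !std::isfinite(vnew[nidx])) {
        unstable = true;
        t_unstable = tnext;
      }
    }
  }

  NumericMatrix host_final(nnode, TNNP_N);
  std::copy(yh.begin(), yh.end(), host_final.begin());
  NumericMatrix donor_final(nocc, nd);
  std::copy(yd.begin(), yd.end(), donor_final.begin());

  return List::create(
      _["time"] = t_out[Range(0, std::max(0, irec - 1))],
      _["v_probe"] = v_probe, _["activation"] = act,
      _["host_final"] = host_final, _["donor_final"] = donor_final,
      _["unstable"] = unstable, _["t_unstable"] = t_unstable);
}
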