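---
title: "Methods: an in silico optogenetic assay of heterocellular coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an in silico optogenetic assay of heterocellular coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The assay

Electrical coupling between cardiomyocytes (CMs) and non-myocytes (nCMs) —
fibroblasts, or grafted stem-cell-derived myocytes — is mediated by
gap-junctional (connexin) channels and is hard to quantify inside
multicellular tissue. The optogenetic-actuator assay simulated by this
package works as follows: the nCMs express channelrhodopsin-2 (ChR2) and
the CMs do not. Light opens ChR2 in the nCMs, depolarizing them; junctional
current then flows into the coupled CM. The minimal irradiance that
triggers a CM action potential, `E_e,th` (mW/mm^2), falls as the
gap-junctional conductance `G_gj` rises (for a passive donor), so `E_e,th`
is a contactless, dose-like readout of coupling strength. The assay
sensitivity metric

    sigma = log10( E_e,th(G_gj) / E_e,th(G_gj,max) ),   G_gj,max = 20 nS

references every threshold to the saturating-coupling value; `sigma = 0`
at 20 nS by construction, and larger magnitudes (either sign) mean a more
sensitive assay. The 20 nS convention is justified empirically: the
package's acceptance suite verifies that `E_e,th` changes by less than 1%
between 19 and 20 nS.

## Cell models

* **Host ventricular CM** — ten Tusscher et al. (2004) human ventricular
  model, epicardial variant: the model used by the fibroblast–myocyte
  coupling framework this assay builds on. 17 states; fast Na+ conductance
  scalable by `ina_fraction` in `[0, 1]` to represent graded I_Na
  blockade (`scale_ina()`).
* **Donor fibroblast** — MacCannell et al. (2007) "active" ventricular
  fibroblast: a time- and voltage-dependent K+ current (gates r/s), an
  inward-rectifier K+ current, an Na+/K+ pump and a background Na+ leak,
  with fixed intracellular concentrations. Membrane capacitance is
  30.8 pF (the experimentally adjusted value for the cells the assay was
  built around; the originally published value is 6.3 pF). The Kv
  conductance (0.25 nS/pF) can be halved or doubled (`g_Kv_scale`) to
  explore different fibroblast resting potentials: doubling
  hyperpolarizes the uncoupled cell (≈ −54.5 mV), halving depolarizes it
  (≈ −42.8 mV) around the default ≈ −49 mV rest.
* **Donor hiPSC-CM** — Paci et al. (2013), ventricular variant. The model
  is spontaneously active through the funny current; in our realization it
  beats at ≈ 0.7 Hz uncoupled, with a maximum diastolic potential near
  −77 mV. The published model is formulated in SI units; the package
  exposes it in mV/ms/mM (1 V/s ≡ 1 mV/ms).
* **ChR2(H134R)** — the four-state photocycle (closed C1/C2, open O1/O2,
  plus a light-adaptation variable `p`), with photocurrent
  `I_ChR2 = g_ChR2 (O1 + gamma O2) G(Vm)`, `g_ChR2 = 0.4` nS/pF,
  `gamma = 0.1`, and rectification `G(Vm) = 10.64 − 14.64 exp(−Vm/42.77)`.
  The channel reversal potential is 0 mV, so this expression already
  contains the driving force; the alternative formulation that divides the
  rectification by `Vm` and multiplies by the driving force `(Vm − 0)` is
  numerically identical away from the removable singularity at 0 mV.
  `chr2_params(variant = "divided")` exposes it anyway, and a test pins
  the equivalence. Every photocycle constant — quantum efficiencies,
  light-dependent inter-open transitions, voltage-dependent closing and
  recovery rates, and the irradiance-to-activation-flux conversion
  (470 nm photons, retinal cross-section 1.2e-19 m^2, loss factor 1.3) —
  is recorded in `chr2_params()`. The light-adaptation gate switches on
  at irradiances above ≈ 1e-3 mW/mm^2 (`theta_scale = 100`); this
  placement is the package's choice and matters because assay thresholds
  extend below 0.1 mW/mm^2: a switch placed near 1 mW/mm^2 would clamp
  all thresholds above it.

## The tandem cell unit

`tcu_config()` couples one host CM to `n_FB` donors (default 5) through
identical ohmic junctions: the current into the host from donor *i* is
`G_gj (V_donor_i − V_host)` in pA, converted to a density with the
receiving cell's capacitance on each side. Donors are mutually uncoupled,
so identically parameterized donors remain exactly synchronous — a
symmetry the tests verify and the tissue model exploits.

**Host-side capacitance.** Converting the absolute junctional current into
the host's pA/pF equation requires the host membrane capacitance, a
quantity the assay's source material does not print and which is not part
of the host model's published current densities. We calibrated it within
the physiological range of human ventricular myocytes (≈ 100–200 pF)
against the three printed coupled-fibroblast resting potentials
(−70.9 / −75.6 / −77.3 mV at 2 / 5 / 10 nS, n_FB = 5), which the default
`host_cm = 165` pF reproduces to within ≈ 0.6 mV after the full 250 s
equilibration. This value also places the assay in the regime the source
experiments report at weak coupling under host I_Na blockade: capture at
2 nS is marginal, which is precisely what makes `sigma` large there. The
absolute threshold scale is the quantity most sensitive to this choice;
relative readouts (`sigma`, curve shapes, orderings) are robust across
100–200 pF.

**Equilibration.** `equilibrate_tcu()` simulates 250 s of coupling with no
stimuli. Human ventricular models with dynamic intracellular Na+/K+ are
not charge-conservative and drift slowly when held quiescent for minutes;
to obtain a true quiescent steady state the host's Na+/K+ concentrations
are held fixed by default (`host_fix_nak = TRUE`; Ca2+ handling stays
dynamic), a standard practice for long quiescent runs. With this guard the
host settles at its published rest (−86.2 mV uncoupled) and the coupled
system reaches `max |dV/dt| < 1e-4 mV/ms` over the final second. For
spontaneously active hiPSC-CM donors the routine flags autorhythmicity
and parks the reference state at the donor's minimum diastolic potential
on the limit cycle; under the default coupled configurations (`G_gj ≥ 2`
nS, five donors against one host) the donor is actually silenced by the
host load and the flag stays off.

## Threshold search and detection

An action potential is detected when the host potential crosses 0 mV
upward within the detection window (500 ms after pulse onset) *and* the
maximal dV/dt in the window is at least 1 mV/ms — the rate guard rejects
slow ChR2-driven plateau drifts without a regenerative upstroke. Both
criteria are configurable in `detect_action_potential()`.

`find_excitation_threshold()` bisects a single optical pulse's irradiance
between a non-capturing and a capturing bracket, starting from [0, 1]
mW/mm^2, expanding the upper end tenfold up to a 100 mW/mm^2 cap (a cap
hit returns an explicit no-capture result), and stopping at 1% relative
width; the reported `E_e,th` is the capturing endpoint, so the invariant
"no AP just below, AP at the threshold" holds by construction. A test
checks the bisection against an exhaustive grid scan on ten
configurations.

**Assay pulse duration.** The duration of the optical pulse used for
sensitivity curves is 50 ms by default. With the H134R photocycle's
closing time constant near 10 ms, a 10 ms pulse saturates — beyond a
moderate irradiance, more light no longer delivers more junctional
charge — and in our realization the weak-coupling/low-excitability corner
(2 nS, host I_Na blocked) then sits above the 100 mW/mm^2 cap. At 50 ms
the full printed parameter space is measurable; strength-duration scans
(`strength_duration_scan()`) expose the duration dependence explicitly,
and every threshold result records the duration used.

## Analytics

* **Strength-duration fits** (`fit_strength_duration()`): the parallel-RC
  form `Irradiance = Rheobase / (1 − exp(−t/Chronaxie))`, or the
  half-time variant with `t log(2)` in the exponent; chronaxies from the
  two variants interconvert by the factor `log(2)` and both are fit by
  Levenberg–Marquardt least squares (ftol/ptol 1e-12; the 2-parameter fit
  converges in far fewer iterations than the optimizer's 1024-iteration
  cap). Deterministic starts: rheobase at the smallest measured
  irradiance, chronaxie at the median duration.
* **Sensitivity curves** (`sensitivity_curve()`): thresholds across a
  `G_gj` grid referenced to 20 nS, with a flag for U-shaped (interior
  minimum) threshold–coupling relationships, which invalidate the
  monotone interpretation of the readout.
* **gapFRAP** (`normalize_frap()`, `fit_frap_recovery()`): fluorescence
  normalized to the first post-bleach frame as zero
  (`(F(t) − F(t0))/F(t0) × 100`), fitted with
  `F(t) = F0 + (F∞ − F0)(1 − exp(−t/τ))`; the coupling index is
  `Dn = 1/τ` reported in 1/s (τ in seconds). Flat traces return a
  non-convergence flag rather than a silent default. The τ start comes
  from a log-linear regression of the residual recovery.

## Synthetic data

`generate_synthetic_sd()` draws the strength-duration form at chosen
durations with multiplicative Gaussian noise (threshold measurement error
scales with the threshold); defaults (rheobase 0.02 mW/mm^2, chronaxie
15 ms, six durations between 2 and 100 ms, 5% noise) emulate a
control-coupling preparation whose thresholds span ≈ 0.02–0.16 mW/mm^2.
`generate_synthetic_frap()` draws mono-exponential recovery on the
standard imaging grid (a frame every 5 s for 195 s) with additive noise;
the default τ = 50 s sits between the printed low- and high-coupling
rates (1/0.014 ≈ 71 s and 1/0.034 ≈ 29 s). These generators emulate curve
shapes and measurement noise only — not photobleaching kinetics, spatial
dye diffusion, or cell-to-cell variability — so fit round-trip tests
demonstrate estimator correctness, not robustness to real-world imaging
artefacts.

## Tissue model

`tissue_grid()` builds a regular 2D monodomain sheet of host CMs with a
circular donor target region. `place_donor_cells()` realizes density `D`
(exactly `ceiling(D × |region|)` nodes) and clustering `C` by iterative
growth: with probability `C` the next occupied node is drawn uniformly
from the unoccupied region-neighbours of the occupied set, otherwise
uniformly from all unoccupied region nodes; seeded and deterministic. At
`C = 0` the occupied-neighbour statistic matches uniform-random sampling
(verified against a direct-sampling oracle); it rises monotonically
through `C = 0.6, 0.9, 0.99`.

Each occupied node carries `n_FB` (default 20) fibroblast+ChR2 donors,
represented by a single donor ODE copy whose junctional current is
multiplied by `n_FB` — exact, because identical mutually uncoupled donors
attached to the same host node see identical inputs. Light reaches donors
only, attenuated as `E(depth) = E0 exp(−depth/δ)` with `δ = 1.84` mm
(488 nm); the `"edge"` illumination mode treats the y coordinate as depth
so a single electrically-2D sheet exercises the attenuation law.

Numerics: operator splitting — a reaction step per node (Rush–Larsen
gates, Euler otherwise) followed by explicit 5-point diffusion with
no-flux boundaries; the constructor enforces the stability bound
`dt ≤ h²/(4 D_diff)`. The default diffusion coefficient 0.1 mm²/ms yields
a planar conduction velocity of ≈ 57 cm/s at 0.2 mm spacing (≈ 61 cm/s at
0.1 mm — a 7% shift; refining further from 0.1 mm changes CV by well
under 5%). An instability detector aborts with diagnostics if any
potential leaves [−150, 150] mV.

`tissue_excitation_threshold()` applies the electrical preamble
(72 pA/pF, 2 ms pulses at an edge strip) to reach a paced quasi-steady
state, then bisects a uniform light pulse exactly as at cell scale;
capture requires activation of ≥ 90% of the sheet (the organ-scale
"global excitation" criterion is not printed; 90% is the package's
choice).

**Desk-scale study conditions.** The test and acceptance runs use a
5 × 5 mm sheet at 0.25 mm spacing with a 2 mm-radius donor region, a
2-stimulus preamble at 400 ms coupling interval, `D = 0.25` and
`n_FB = 20`. The pattern comparison runs across `C ∈ {0.6, 0.9, 0.99}`
at `G_gj = 5` nS (the conductance at which every pattern captures on a
sheet this small — dispersed placements at 2 nS sit beyond the
irradiance cap because the sheet is a far smaller current sink than a
ventricle), and the coupling comparison across `G_gj ∈ {2, 10}` nS at
`C = 0.9`. These sizes keep a full threshold bisection within minutes on
one CPU while preserving the organ-scale phenomenology: the spatial
pattern moves `E_e,th` far less (≈ 0.36 relative spread) than the
junctional conductance does (≈ 2.6 over 2–10 nS), and `n_FB = 5` TCUs
fail to capture at all (source–sink mismatch).

## Numerical choices

* Fixed-step integration: forward Euler for membrane potential and
  concentrations, Rush–Larsen exponential updates for Hodgkin–Huxley
  gates, and sub-stepped explicit Euler for the (conservative) ChR2
  occupancies with the sub-step tied to the fastest light-dependent rate.
  Steps: 0.02 ms for stimulated runs, 0.05–0.1 ms for quiescent
  equilibration (0.05 vs 0.1 ms changes coupled resting potentials by
  ≈ 0.02 mV and thresholds by ≈ 2%). A deSolve/lsoda integration of the
  same right-hand sides serves as the accuracy oracle in the tests.
* Free Ca2+ concentrations are floored at 1e-9 mM: explicit Euler can
  otherwise step the quiescent Ca2+ transient below zero, where the
  models' fractional powers are undefined.
* ChR2 occupancies evolve conservatively by construction; conservation is
  asserted to 1e-6 along trajectories.
* Ties and degenerate inputs: zero-amplitude optical pulses are exact
  no-ops; `G_gj = 0` reduces every cell to its uncoupled steady state;
  flat FRAP traces and sub-3-point strength-duration tables are rejected
  or flagged, never silently fit.

## Known limitations

* The host-model variant, host capacitance, ChR2 rate constants and the
  assay pulse duration for the sensitivity analyses are not printed in
  the assay's source material; the package documents its choices above.
  Absolute `E_e,th` values are sensitive to these choices (tens of
  percent); relative quantities — `sigma`, orderings, curve shapes — are
  the robust readouts, mirroring how the assay is meant to be used
  ("relative reporting").
* In our realization, reducing hiPSC-CM donor excitability to 20–30%
  I_Na produces a threshold–coupling curve with an interior *maximum*
  (both mechanisms of excitation — donor-AP-mediated at weak coupling and
  direct junctional drive at strong coupling — remain available), rather
  than the interior minimum reported for the original model chain. The
  acceptance suite asserts the reported shape and documents this
  divergence rather than masking it.
* The tissue model is a regular isotropic 2D sheet: no fibre
  architecture, no bidomain effects, no MRI anatomy, no ECG.
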