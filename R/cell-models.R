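## Cell-model parameter constructors, default states and right-hand sides.
##
## Conventions: membrane potential mV, time ms, current densities pA/pF,
## conductance densities nS/pF, concentrations mM. A positive injected
## current depolarizes.

# ---------------------------------------------------------------------------
# ChR2 photocycle (four-state H134R model)
# ---------------------------------------------------------------------------

#' ChR2(H134R) photocycle parameters
#'
#' Parameters of the four-state channelrhodopsin-2 photocycle (closed states
#' C1/C2, open states O1/O2 plus a light-adaptation variable `p`). The
#' photocurrent is `I_ChR2 = g_ChR2 (O1 + gamma O2) G(Vm)` with the
#' voltage-dependent rectification `G(Vm) = a - b exp(-Vm/c)`; the reversal
#' potential of the channel is 0 mV, so the printed rectification expression
#' already contains the driving force and the `"divided"` variant
#' (`G(Vm)/Vm` times the driving force `Vm - 0`) is numerically identical
#' away from `Vm = 0`.
#'
#' Light enters through the effective activation rate
#' `k1 = eps1 * F * p`, `k2 = eps2 * F * p`, where
#' `F = sigma_retinal * phi / w_loss` and `phi` is the photon flux derived
#' from the irradiance (mW/mm^2) at `wavelength_nm`.
#'
#' @param g_chr2 maximal channel conductance density, nS/pF
#' @param gamma ratio of dark- to light-adapted open-channel conductance
#' @param rect_a,rect_b,rect_c rectification coefficients (mV for `rect_c`)
#' @param eps1,eps2 quantum efficiencies of the two activation transitions
#' @param e12_dark,e21_dark dark inter-open transition rates, 1/ms
#' @param c1,c2 light sensitivities of the inter-open transitions, 1/ms
#' @param i_half irradiance scale of the logarithmic light dependence,
#'   mW/mm^2
#' @param wavelength_nm stimulation wavelength, nm
#' @param sigma_retinal retinal absorption cross-section, m^2
#' @param w_loss protein/membrane loss factor of the photon flux
#' @param tau_p time constant of the light-adaptation variable, ms
#' @param theta_scale scaling of irradiance into the adaptation switch
#'   argument (per mW/mm^2); the default turns adaptation fully on for any
#'   irradiance above ~1e-3 mW/mm^2
#' @param variant `"printed"` uses `G(Vm) = a - b exp(-Vm/c)` directly;
#'   `"divided"` divides by `Vm` and multiplies by the driving force
#' @return an object of class `chr2_params`
#' @export
chr2_params <- function(g_chr2 = 0.4, gamma = 0.1,
                        rect_a = 10.64, rect_b = 14.64, rect_c = 42.77,
                        eps1 = 0.8535, eps2 = 0.14,
                        e12_dark = 0.011, c1 = 0.005,
                        e21_dark = 0.008, c2 = 0.004,
                        i_half = 0.024,
                        wavelength_nm = 470, sigma_retinal = 1.2e-19,
                        w_loss = 1.3, tau_p = 1.3, theta_scale = 100,
                        variant = c("printed", "divided")) {
  variant <- match.arg(variant)
  stopifnot(g_chr2 > 0, gamma >= 0, gamma <= 1, rect_c > 0, i_half > 0,
            tau_p > 0, w_loss > 0)
  hc <- 6.62607015e-34 * 2.99792458e8              # J m
  photon_energy <- hc / (wavelength_nm * 1e-9)     # J
  # photons m^-2 ms^-1 per mW/mm^2 (1 mW/mm^2 = 1000 W/m^2)
  phi_per_irr <- 1000 / photon_energy / 1000
  flux_factor <- sigma_retinal * phi_per_irr / w_loss  # 1/ms per mW/mm^2
  structure(list(
    g_chr2 = g_chr2, gamma = gamma,
    rect_a = rect_a, rect_b = rect_b, rect_c = rect_c,
    eps1 = eps1, eps2 = eps2, e12_dark = e12_dark, c1 = c1,
    e21_dark = e21_dark, c2 = c2, i_half = i_half,
    wavelength_nm = wavelength_nm, sigma_retinal = sigma_retinal,
    w_loss = w_loss, flux_factor = flux_factor, tau_p = tau_p,
    theta_scale = theta_scale, variant = variant
  ), class = "chr2_params")
}

# parameter vector layout expected by the compiled core
as_chr2_vec <- function(p) {
  c(p$g_chr2, p$gamma, p$rect_a, p$rect_b, p$rect_c, p$eps1, p$eps2,
    p$e12_dark, p$c1, p$e21_dark, p$c2, p$i_half, p$flux_factor, p$tau_p,
    p$theta_scale, if (p$variant == "divided") 1 else 0)
}

#' Default ChR2 state (dark-adapted, all channels in C1)
#' @return named numeric vector `(O1, O2, C1, C2, p)`
#' @export
chr2_state <- function() {
  y <- chr2_init_cpp()
  names(y) <- c("O1", "O2", "C1", "C2", "p")
  y
}

#' ChR2 voltage-dependent rectification factor
#'
#' Evaluates `G(Vm) = a - b exp(-Vm/c)` (unitless).
#'
#' @param vm membrane potential, mV (vectorized)
#' @param params [chr2_params()]
#' @return rectification factor(s)
#' @export
eval_rectification <- function(vm, params = chr2_params()) {
  stopifnot(all(is.finite(vm)))
  vapply(vm, chr2_rect_cpp, numeric(1), pars = as_chr2_vec(params))
}

#' ChR2 photocurrent density
#'
#' `I_ChR2 = g_ChR2 (O1 + gamma O2) G(Vm)`, pA/pF. Negative (inward) for
#' membrane potentials well below the 0 mV channel reversal.
#'
#' @param state named ChR2 state vector (see [chr2_state()])
#' @param vm membrane potential, mV
#' @param params [chr2_params()]
#' @return current density, pA/pF
#' @export
chr2_current <- function(state, vm, params = chr2_params()) {
  check_chr2_state(state)
  chr2_current_cpp(state[["O1"]], state[["O2"]], vm, as_chr2_vec(params))
}

check_chr2_state <- function(state, tol = 1e-6) {
  occ <- state[c("O1", "O2", "C1", "C2")]
  if (any(occ < -tol) || any(occ > 1 + tol))
    stop("ChR2 occupancies must lie in [0, 1]")
  if (abs(sum(occ) - 1) > 1e-4)
    stop("ChR2 occupancies must sum to 1")
  invisible(state)
}

#' ChR2 photocycle right-hand side
#'
#' Time derivatives of the photocycle state at a given irradiance and
#' membrane potential. The four occupancy derivatives sum to zero
#' (conservation of channels).
#'
#' @param state named ChR2 state vector
#' @param irradiance light irradiance, mW/mm^2 (must be non-negative)
#' @param vm membrane potential, mV
#' @param params [chr2_params()]
#' @return named derivative vector, 1/ms
#' @export
chr2_rhs <- function(state, irradiance, vm, params = chr2_params()) {
  if (irradiance < 0) stop("irradiance must be non-negative")
  dy <- chr2_rhs_cpp(unname(state), as_chr2_vec(params), vm, irradiance)
  names(dy) <- c("O1", "O2", "C1", "C2", "p")
  dy
}

# ---------------------------------------------------------------------------
# MacCannell active fibroblast
# ---------------------------------------------------------------------------

#' Fibroblast (MacCannell active model) parameters
#'
#' The active ventricular fibroblast model carries a time- and
#' voltage-dependent K+ current (I_Kv, gates r/s), an inward-rectifier K+
#' current, an Na+/K+ pump and a background Na+ leak; intracellular
#' concentrations are fixed. The membrane capacitance default (30.8 pF) is
#' the experimentally adjusted value used by the assay; the original
#' published value is 6.3 pF.
#'
#' @param Cm membrane capacitance, pF
#' @param g_Kv conductance density of the time/voltage-dependent K+ current,
#'   nS/pF
#' @param g_Kv_scale multiplicative scale on `g_Kv` (0.5 / 1 / 2 used to
#'   explore different fibroblast resting potentials)
#' @param g_K1,g_bNa conductance densities, nS/pF
#' @param i_NaK_max maximal Na+/K+ pump current, pA/pF
#' @param Km_K,Km_Na pump half-saturation constants, mM
#' @param V_rev,B pump voltage-dependence parameters, mV
#' @param K_o,K_i,Na_o,Na_i fixed ionic concentrations, mM
#' @return an object of class `fibroblast_params`
#' @export
fibroblast_params <- function(Cm = 30.8, g_Kv = 0.25, g_Kv_scale = 1,
                              g_K1 = 0.4822, g_bNa = 0.0095,
                              i_NaK_max = 2.002, Km_K = 1.0, Km_Na = 11.0,
                              V_rev = -150, B = -200,
                              K_o = 5.4, K_i = 129.4349,
                              Na_o = 130.011, Na_i = 8.5547) {
  stopifnot(Cm > 0, g_Kv >= 0, g_Kv_scale >= 0)
  structure(list(
    Cm = Cm, g_Kv = g_Kv, g_Kv_scale = g_Kv_scale, g_K1 = g_K1,
    g_bNa = g_bNa, i_NaK_max = i_NaK_max, Km_K = Km_K, Km_Na = Km_Na,
    V_rev = V_rev, B = B, K_o = K_o, K_i = K_i, Na_o = Na_o, Na_i = Na_i
  ), class = "fibroblast_params")
}

as_fib_vec <- function(p) {
  c(p$Cm, p$g_Kv * p$g_Kv_scale, p$g_K1, p$g_bNa, p$i_NaK_max, p$Km_K,
    p$Km_Na, p$V_rev, p$B, p$K_o, p$K_i, p$Na_o, p$Na_i)
}

#' Default fibroblast state
#' @return named numeric vector `(V, r, s)`
#' @export
fibroblast_state <- function() {
  y <- fib_init_cpp()
  names(y) <- c("V", "r", "s")
  y
}

#' Fibroblast right-hand side
#'
#' @param state named fibroblast state `(V, r, s)`
#' @param i_in injected/junctional current in pA (converted to a density
#'   with the fibroblast capacitance; positive depolarizes)
#' @param params [fibroblast_params()]
#' @return named derivative vector (`V` in mV/ms; gates 1/ms)
#' @export
fibroblast_rhs <- function(state, i_in = 0, params = fibroblast_params()) {
  dy <- fib_rhs_cpp(unname(state), as_fib_vec(params), i_in / params$Cm)
  names(dy) <- c("V", "r", "s")
  dy
}

# ---------------------------------------------------------------------------
# Host ventricular myocyte (ten Tusscher 2004 epicardial)
# ---------------------------------------------------------------------------

#' Host ventricular myocyte parameters
#'
#' The host cardiomyocyte is the ten Tusscher et al. 2004 human ventricular
#' model, epicardial variant (the model used in the fibroblast-myocyte
#' coupling framework the assay builds on). The full constant set is
#' compiled into the package; this constructor exposes the constants for
#' reference together with the fast-Na+ scale factor used to model graded
#' excitability (progressive I_Na blockade).
#'
#' @param ina_fraction scale in `[0, 1]` applied to the fast Na+ conductance
#' @return an object of class `myocyte_params`
#' @export
myocyte_params <- function(ina_fraction = 1) {
  stopifnot(ina_fraction >= 0, ina_fraction <= 1)
  structure(list(
    ina_fraction = ina_fraction, Cm = 185,
    g_Na = 14.838, g_K1 = 5.405, g_Kr = 0.096, g_Ks = 0.245, g_to = 0.294,
    g_CaL = 1.75e-4, g_bNa = 0.00029, g_bCa = 0.000592, g_pCa = 0.825,
    g_pK = 0.0146, P_NaK = 1.362, k_NaCa = 1000,
    K_o = 5.4, Na_o = 140, Ca_o = 2
  ), class = "myocyte_params")
}

#' Default host myocyte state
#' @return named numeric vector of the 17 model states
#' @export
myocyte_state <- function() {
  y <- tnnp_init_cpp()
  names(y) <- tnnp_state_names()
  y
}

tnnp_state_names <- function() {
  c("V", "m", "h", "j", "d", "f", "fCa", "r", "s", "xs", "xr1", "xr2", "g",
    "Cai", "CaSR", "Nai", "Ki")
}

#' Host myocyte right-hand side
#'
#' @param state named 17-element state vector (see [myocyte_state()])
#' @param i_in junctional/other current density, pA/pF (positive
#'   depolarizes; affects the membrane equation only)
#' @param i_stim electrode stimulus current density, pA/pF (enters the K+
#'   bookkeeping as in the published model)
#' @param params [myocyte_params()]
#' @return named derivative vector
#' @export
host_cm_rhs <- function(state, i_in = 0, i_stim = 0,
                        params = myocyte_params()) {
  dy <- tnnp_rhs_cpp(unname(state), i_stim, i_in, params$ina_fraction)
  names(dy) <- tnnp_state_names()
  dy
}

# ---------------------------------------------------------------------------
# Donor hiPSC-CM (Paci 2013 ventricular)
# ---------------------------------------------------------------------------

#' Donor hiPSC-CM parameters (Paci ventricular variant)
#'
#' The excitable donor cell model is the ventricular variant of the Paci
#' et al. hiPSC-derived cardiomyocyte model. It is spontaneously active
#' (funny current If); constants are compiled into the package and exposed
#' here for reference.
#'
#' @param ina_fraction scale in `[0, 1]` applied to the fast Na+ conductance
#' @return an object of class `ipsc_cm_params`
#' @export
ipsc_cm_params <- function(ina_fraction = 1) {
  stopifnot(ina_fraction >= 0, ina_fraction <= 1)
  structure(list(
    ina_fraction = ina_fraction, Cm = 98.7109,
    g_Na = 3671.2302, g_CaL = 8.635702e-5, g_Kr = 29.8667, g_Ks = 2.041,
    g_K1 = 28.1492, g_f = 30.10312, g_to = 29.9038,
    K_o = 5.4, Na_o = 151, Ca_o = 1.8, K_i = 150
  ), class = "ipsc_cm_params")
}

#' Default donor hiPSC-CM state
#' @return named numeric vector of the 18 model states
#' @export
ipsc_cm_state <- function() {
  y <- paci_init_cpp()
  names(y) <- paci_state_names()
  y
}

paci_state_names <- function() {
  c("V", "m", "h", "j", "d", "f1", "f2", "fCa", "Xr1", "Xr2", "Xs", "Xf",
    "q", "r", "g", "Cai", "CaSR", "Nai")
}

#' Donor hiPSC-CM right-hand side
#'
#' @param state named 18-element state vector (see [ipsc_cm_state()])
#' @param i_in junctional/other current density, pA/pF
#' @param i_stim stimulus current density, pA/pF
#' @param params [ipsc_cm_params()]
#' @return named derivative vector
#' @export
donor_ipsc_cm_rhs <- function(state, i_in = 0, i_stim = 0,
                              params = ipsc_cm_params()) {
  dy <- paci_rhs_cpp(unname(state), i_in + i_stim, params$ina_fraction)
  names(dy) <- paci_state_names()
  dy
}

#' Scale the fast Na+ conductance of an excitable cell model
#'
#' Multiplies the fast Na+ conductance by `fraction`, leaving every other
#' parameter unchanged (models progressive I_Na blockade).
#'
#' @param params [myocyte_params()] or [ipsc_cm_params()]
#' @param fraction scale factor in `[0, 1]`
#' @return parameters of the same class with `g_Na` (and the compiled
#'   `ina_fraction`) scaled
#' @export
scale_ina <- function(params, fraction) {
  stopifnot(inherits(params, c("myocyte_params", "ipsc_cm_params")),
            fraction >= 0, fraction <= 1)
  params$g_Na <- params$g_Na * fraction
  params$ina_fraction <- params$ina_fraction * fraction
  params
}
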