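## Stimulus descriptions and the single-cell runner.

#' Describe a pulsed stimulus
#'
#' @param modality `"optical"` (irradiance, mW/mm^2, drives ChR2) or
#'   `"electrical"` (current density, pA/pF)
#' @param amplitude pulse amplitude (mW/mm^2 or pA/pF; non-negative)
#' @param pulse_duration pulse duration, ms (positive)
#' @param period pulse period, ms (0 for a single pulse)
#' @param n_pulses number of pulses
#' @param onset time of the first pulse, ms
#' @return an object of class `stimulus_protocol`
#' @export
stimulus_protocol <- function(modality = c("optical", "electrical"),
                              amplitude, pulse_duration, period = 0,
                              n_pulses = 1, onset = 0) {
  modality <- match.arg(modality)
  stopifnot(amplitude >= 0, pulse_duration > 0, n_pulses >= 1, onset >= 0,
            period == 0 || period >= pulse_duration)
  structure(list(modality = modality, amplitude = amplitude,
                 pulse_duration = pulse_duration, period = period,
                 n_pulses = n_pulses, onset = onset),
            class = "stimulus_protocol")
}

no_stimulus <- function() c(0, 0, 0, 0, 0)

as_stim_vec <- function(protocol) {
  if (is.null(protocol)) return(no_stimulus())
  stopifnot(inherits(protocol, "stimulus_protocol"))
  c(protocol$amplitude, protocol$pulse_duration, protocol$period,
    protocol$n_pulses, protocol$onset)
}

#' Integrate a single cell model
#'
#' Runs one cell (optionally carrying a ChR2 block) under optical and/or
#' electrical stimulation with the package's fixed-step integrator
#' (forward Euler membrane/concentration updates, Rush-Larsen gates).
#'
#' @param cell `"myocyte"` (host ventricular CM), `"ipsc_cm"` (donor
#'   hiPSC-CM) or `"fibroblast"`
#' @param duration simulation length, ms
#' @param state initial state (defaults to the model's published initial
#'   conditions); if a ChR2 block is attached the ChR2 states are appended
#' @param params model parameters ([myocyte_params()], [ipsc_cm_params()]
#'   or [fibroblast_params()])
#' @param chr2 [chr2_params()] to attach a ChR2 photocurrent, or `NULL`
#' @param optical,electrical [stimulus_protocol()] objects or `NULL`
#' @param fix_nak for the host myocyte: hold intracellular Na+/K+ fixed
#'   (drift guard for long quiescent runs); ignored for other cell types
#' @param dt integration step, ms
#' @param record_dt output sampling interval, ms
#' @return a data.frame `(time, v, i_chr2)` with the final full state in
#'   attribute `"final"`
#' @export
simulate_cell <- function(cell = c("myocyte", "ipsc_cm", "fibroblast"),
                          duration, state = NULL, params = NULL,
                          chr2 = NULL, optical = NULL, electrical = NULL,
                          fix_nak = FALSE, dt = 0.02, record_dt = 0.5) {
  cell <- match.arg(cell)
  type <- switch(cell, myocyte = 1L, ipsc_cm = 2L, fibroblast = 3L)
  if (is.null(params)) {
    params <- switch(cell, myocyte = myocyte_params(),
                     ipsc_cm = ipsc_cm_params(),
                     fibroblast = fibroblast_params())
  }
  chr2_on <- !is.null(chr2)
  if (is.null(state)) {
    state <- switch(cell, myocyte = myocyte_state(),
                    ipsc_cm = ipsc_cm_state(),
                    fibroblast = fibroblast_state())
    if (chr2_on) state <- c(state, chr2_state())
  }
  ina <- if (cell == "fibroblast") 1 else params$ina_fraction
  fib_vec <- if (cell == "fibroblast") as_fib_vec(params) else numeric(13)
  chr2_vec <- if (chr2_on) as_chr2_vec(chr2) else numeric(16)
  if (!is.null(optical) && optical$modality != "optical")
    stop("`optical` must be an optical stimulus")
  if (!is.null(electrical) && electrical$modality != "electrical")
    stop("`electrical` must be an electrical stimulus")

  res <- cell_run_cpp(type, unname(state), fib_vec, chr2_vec, chr2_on, ina,
                      fix_nak, as_stim_vec(electrical), as_stim_vec(optical),
                      duration, dt, record_dt)
  out <- data.frame(time = res$time, v = res$v, i_chr2 = res$i_chr2)
  final <- res$final
  names(final) <- names(state)
  attr(out, "final") <- final
  out
}
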