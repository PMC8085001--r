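## Tandem cell unit (TCU) engine: configuration, equilibration, stimulation,
## action-potential detection, excitation-threshold bisection,
## strength-duration scans and sensor-mode metrics.

#' Configure a tandem cell unit
#'
#' A TCU couples one host ventricular cardiomyocyte to `n_fb` donor cells
#' (fibroblasts or hiPSC-CMs) through identical ohmic gap-junctional
#' conductances `g_gj` (nS). Donor cells are mutually uncoupled. Only donors
#' carry the ChR2 photocurrent.
#'
#' @param donor_type `"fibroblast"` or `"ipsc_cm"`
#' @param n_fb number of donor cells (>= 1)
#' @param g_gj per-junction gap-junctional conductance, nS
#' @param donor_ina_fraction,host_ina_fraction fast-Na+ scale factors in
#'   `[0, 1]` (the fibroblast donor has no fast Na+ current; its value is
#'   ignored for that donor type)
#' @param g_kv_scale scale on the fibroblast Kv conductance (0.5 / 1 / 2)
#' @param chr2 logical; attach ChR2 to the donors
#' @param host_cm host membrane capacitance used to convert absolute
#'   junctional current to a density, pF
#' @param host_fix_nak hold the host's intracellular Na+/K+ concentrations
#'   fixed (guards against the slow drift of the non-conservative ionic
#'   formulation over long quiescent equilibrations; Ca2+ handling stays
#'   dynamic)
#' @param chr2_params,fib_params model parameter objects
#' @param dt integration step for stimulated runs, ms
#' @param dt_equil integration step for the quiescent equilibration, ms
#' @return an object of class `tcu_config`
#' @export
tcu_config <- function(donor_type = c("fibroblast", "ipsc_cm"), n_fb = 5,
                       g_gj = 2, donor_ina_fraction = 1,
                       host_ina_fraction = 1, g_kv_scale = 1, chr2 = TRUE,
                       host_cm = 165, host_fix_nak = TRUE,
                       chr2_params = optogap::chr2_params(),
                       fib_params = NULL, dt = 0.02, dt_equil = 0.05) {
  donor_type <- match.arg(donor_type)
  stopifnot(n_fb >= 1, g_gj >= 0,
            donor_ina_fraction >= 0, donor_ina_fraction <= 1,
            host_ina_fraction >= 0, host_ina_fraction <= 1,
            g_kv_scale > 0, host_cm > 0, dt > 0, dt_equil > 0)
  if (is.null(fib_params)) fib_params <- fibroblast_params(g_Kv_scale = g_kv_scale)
  structure(list(
    donor_type = donor_type, host_type = "ventricular_cm", n_fb = n_fb,
    g_gj = g_gj, donor_ina_fraction = donor_ina_fraction,
    host_ina_fraction = host_ina_fraction, g_kv_scale = g_kv_scale,
    chr2 = chr2, host_cm = host_cm, host_fix_nak = host_fix_nak,
    chr2_params = chr2_params,
    fib_params = fib_params,
    dt = dt, dt_equil = dt_equil
  ), class = "tcu_config")
}

donor_type_code <- function(config) {
  switch(config$donor_type, ipsc_cm = 2L, fibroblast = 3L)
}

donor_default_state <- function(config) {
  base <- switch(config$donor_type, fibroblast = fibroblast_state(),
                 ipsc_cm = ipsc_cm_state())
  if (config$chr2) base <- c(base, chr2_state())
  base
}

default_tcu_states <- function(config) {
  d0 <- donor_default_state(config)
  donors <- matrix(rep(unname(d0), each = config$n_fb), nrow = config$n_fb)
  colnames(donors) <- names(d0)
  list(host = myocyte_state(), donors = donors)
}

run_tcu <- function(config, states, optical = NULL, electrical = NULL,
                    duration, dt, record_dt) {
  tcu_run_cpp(1L, unname(states$host), donor_type_code(config),
              states$donors, config$chr2, as_fib_vec(config$fib_params),
              as_chr2_vec(config$chr2_params), config$host_ina_fraction,
              config$donor_ina_fraction, config$g_gj, config$host_cm,
              config$host_fix_nak, as_stim_vec(optical),
              as_stim_vec(electrical), duration, dt, record_dt)
}

res_states <- function(config, res, template) {
  host <- res$host_final
  names(host) <- tnnp_state_names()
  donors <- res$donor_final
  colnames(donors) <- colnames(template$donors)
  list(host = host, donors = donors)
}

#' Equilibrate a tandem cell unit
#'
#' Simulates `duration` ms (default 250 s) of electrical coupling with no
#' stimuli to attain a quiescent steady state. For spontaneously active
#' donors (hiPSC-CM) the configuration is flagged as autorhythmic and the
#' returned reference state is taken at the donor's minimum diastolic
#' potential on the limit cycle.
#'
#' @param config [tcu_config()]
#' @param duration equilibration length, ms
#' @return an object of class `tcu_states`: host/donor state vectors plus
#'   `v_rest_host`, `v_rest_donor`, `autorhythmic` and `max_dvdt` (maximum
#'   absolute host dV/dt over the final second, mV/ms)
#' @export
equilibrate_tcu <- function(config, duration = 250e3) {
  stopifnot(inherits(config, "tcu_config"), duration > 2000)
  st0 <- default_tcu_states(config)
  main <- run_tcu(config, st0, duration = duration - 1000,
                  dt = config$dt_equil, record_dt = duration)
  st1 <- res_states(config, main, st0)
  tail <- run_tcu(config, st1, duration = 1000, dt = config$dt_equil,
                  record_dt = 1)
  st <- res_states(config, tail, st0)

  dvdt_host <- max(abs(diff(tail$v_host)))        # record_dt = 1 ms
  vd <- tail$v_donor
  autorhythmic <- (max(vd) - min(vd)) > 10

  if (autorhythmic) {
    # park the reference state at the donor minimum diastolic potential
    scan <- run_tcu(config, st, duration = 4000, dt = config$dt_equil,
                    record_dt = 1)
    vmin_idx <- which.min(scan$v_donor[, 1])
    t_mdp <- scan$time[vmin_idx]
    if (t_mdp > 0) {
      seg <- run_tcu(config, st, duration = t_mdp, dt = config$dt_equil,
                     record_dt = t_mdp)
      st <- res_states(config, seg, st0)
    }
    warning("donor cells are autorhythmic; returning limit-cycle state at ",
            "the donor minimum diastolic potential",
            call. = FALSE)
  } else if (dvdt_host > 1e-4) {
    warning(sprintf(
      "host |dV/dt| over the final second (%.2g mV/ms) exceeds the quiescence tolerance",
      dvdt_host), call. = FALSE)
  }

  structure(list(
    host = st$host, donors = st$donors, config = config,
    duration = duration, autorhythmic = autorhythmic,
    v_rest_host = st$host[["V"]], v_rest_donor = unname(st$donors[, "V"]),
    max_dvdt = dvdt_host
  ), class = "tcu_states")
}

#' Simulate a tandem cell unit
#'
#' Integrates the composed TCU system from given states under an optical
#' and/or electrical stimulus. The junctional current into the host from
#' donor i is `G_gj (V_donor_i - V_host)` (pA) and its negative enters
#' donor i; each is converted to a density with the receiving cell's
#' capacitance.
#'
#' @param config [tcu_config()]
#' @param states a `tcu_states` object (from [equilibrate_tcu()]) or a
#'   list with `host` and `donors` entries
#' @param protocol a [stimulus_protocol()] (optical stimuli drive donor
#'   ChR2; electrical stimuli drive the host), or a list of protocols,
#'   or `NULL`
#' @param duration simulated time, ms
#' @param record_dt output sampling interval, ms
#' @return an object of class `tcu_trace`: a data.frame with `time` (ms),
#'   `v_host`, donor potentials `v_donor_1..n` (mV), net junctional current
#'   into the host `i_gj` (pA), mean donor ChR2 current density `i_chr2`
#'   (pA/pF) and the applied `irradiance`; final states in attribute
#'   `"final"`
#' @export
simulate_tcu <- function(config, states, protocol = NULL, duration,
                         record_dt = 0.2) {
  if (inherits(protocol, "stimulus_protocol")) protocol <- list(protocol)
  optical <- NULL; electrical <- NULL
  for (p in protocol) {
    if (p$modality == "optical") optical <- p else electrical <- p
  }
  res <- run_tcu(config, states, optical, electrical, duration,
                 dt = config$dt, record_dt = record_dt)
  vd <- res$v_donor
  colnames(vd) <- paste0("v_donor_", seq_len(ncol(vd)))
  out <- data.frame(time = res$time, v_host = res$v_host, vd,
                    i_gj = res$i_gj, i_chr2 = res$i_chr2,
                    irradiance = res$irradiance)
  attr(out, "final") <- res_states(config, res,
                                   list(donors = states$donors))
  attr(out, "config") <- config
  class(out) <- c("tcu_trace", "data.frame")
  out
}

#' Detect an action potential in a host voltage trace
#'
#' Detection criterion: the host membrane potential crosses `threshold_v`
#' (default 0 mV) upward within the window, and the maximum dV/dt within
#' the window is at least `min_dvdt` (default 1 mV/ms). The dV/dt guard
#' rejects slow ChR2-driven plateau depolarizations that drift across 0 mV
#' without a regenerative upstroke.
#'
#' @param trace a `tcu_trace` (or any data.frame with `time` and `v_host`)
#' @param window numeric length-2 time window, ms (default: whole trace)
#' @param threshold_v voltage criterion, mV
#' @param min_dvdt upstroke-rate criterion, mV/ms
#' @return list with `detected` (logical), `upstroke_times` (ms) and
#'   `max_dvdt` (mV/ms)
#' @export
detect_action_potential <- function(trace, window = NULL, threshold_v = 0,
                                    min_dvdt = 1) {
  t <- trace$time
  v <- if (!is.null(trace$v_host)) trace$v_host else trace$v
  if (is.null(window)) window <- range(t)
  keep <- t >= window[1] & t <= window[2]
  t <- t[keep]; v <- v[keep]
  if (length(t) < 3)
    return(list(detected = FALSE, upstroke_times = numeric(0),
                max_dvdt = NA_real_))
  dvdt <- diff(v) / diff(t)
  cross <- which(v[-length(v)] <= threshold_v & v[-1] > threshold_v)
  detected <- length(cross) > 0 && max(dvdt) >= min_dvdt
  list(detected = detected,
       upstroke_times = t[cross + 1],
       max_dvdt = max(dvdt))
}

#' Find the optical excitation threshold of a tandem cell unit
#'
#' Bisects the irradiance of a single optical pulse to the weakest stimulus
#' that elicits a host action potential, the assay readout `E_e,th`
#' (mW/mm^2). The upper bracket is auto-expanded (x10) up to `cap`; if no
#' capture occurs at the cap the result is flagged `no_capture`.
#'
#' @param config [tcu_config()]
#' @param pulse_duration optical pulse duration, ms
#' @param states pre-equilibrated `tcu_states`; if `NULL`,
#'   [equilibrate_tcu()] is run first
#' @param bracket initial irradiance bracket, mW/mm^2
#' @param rel_tol relative bisection tolerance on `E_e,th`
#' @param cap maximal tested irradiance, mW/mm^2
#' @param window AP detection window after pulse onset, ms
#' @param onset pulse onset time within each simulation, ms
#' @param record_dt trace sampling, ms
#' @param equil_duration equilibration length used when `states` is `NULL`,
#'   ms
#' @return an object of class `threshold_result`: `e_th`, `no_capture`,
#'   final `bracket`, `iterations` and the detection records at the final
#'   bracket endpoints
#' @export
find_excitation_threshold <- function(config, pulse_duration = 50,
                                      states = NULL, bracket = c(0, 1),
                                      rel_tol = 0.01, cap = 100,
                                      window = 500, onset = 10,
                                      record_dt = 0.2,
                                      equil_duration = 250e3) {
  stopifnot(inherits(config, "tcu_config"), config$chr2,
            bracket[1] >= 0, bracket[2] > bracket[1], rel_tol > 0)
  if (is.null(states)) states <- equilibrate_tcu(config, equil_duration)
  duration <- onset + max(window, pulse_duration) + 10

  has_ap <- function(e) {
    prot <- if (e > 0)
      stimulus_protocol("optical", e, pulse_duration, onset = onset)
    tr <- simulate_tcu(config, states, prot, duration, record_dt)
    detect_action_potential(tr, window = c(onset, onset + window))
  }

  det_low <- has_ap(bracket[1])
  if (det_low$detected)
    stop("action potential detected at the lower bracket; ",
         "the configuration fires without light in the detection window")

  lo <- bracket[1]; hi <- bracket[2]; iter <- 0L
  det_hi <- has_ap(hi)
  while (!det_hi$detected && hi < cap) {
    lo <- hi
    hi <- min(10 * hi, cap)
    det_hi <- has_ap(hi)
    iter <- iter + 1L
  }
  if (!det_hi$detected) {
    return(structure(list(
      e_th = NA_real_, no_capture = TRUE, bracket = c(lo, hi),
      iterations = iter, detect_low = det_low, detect_high = det_hi,
      pulse_duration = pulse_duration, config = config
    ), class = "threshold_result"))
  }

  while ((hi - lo) > rel_tol * hi) {
    mid <- (lo + hi) / 2
    det <- has_ap(mid)
    if (det$detected) {
      hi <- mid; det_hi <- det
    } else {
      lo <- mid; det_low <- det
    }
    iter <- iter + 1L
  }

  structure(list(
    e_th = hi, no_capture = FALSE, bracket = c(lo, hi), iterations = iter,
    detect_low = det_low, detect_high = det_hi,
    pulse_duration = pulse_duration, config = config
  ), class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  if (x$no_capture) {
    cat("optical excitation threshold: no capture up to",
        x$bracket[2], "mW/mm^2\n")
  } else {
    cat(sprintf("optical excitation threshold E_e,th = %.4g mW/mm^2 (%g ms pulse, %d bisection simulations)\n",
                x$e_th, x$pulse_duration, x$iterations))
  }
  invisible(x)
}

#' Strength-duration scan of the optical excitation threshold
#'
#' Finds `E_e,th` for each optical pulse duration, reusing a single
#' equilibrated state.
#'
#' @param config [tcu_config()]
#' @param durations optical pulse durations, ms
#' @param states optional pre-equilibrated `tcu_states`
#' @param ... passed to [find_excitation_threshold()]
#' @return a `strength_duration_curve` data.frame with columns
#'   `duration_ms`, `irradiance_mW_mm2` and `no_capture`
#' @export
strength_duration_scan <- function(config, durations, states = NULL, ...) {
  if (is.null(states)) states <- equilibrate_tcu(config)
  res <- lapply(durations, function(d)
    find_excitation_threshold(config, pulse_duration = d, states = states,
                              ...))
  out <- data.frame(
    duration_ms = durations,
    irradiance_mW_mm2 = vapply(res, function(r) r$e_th, numeric(1)),
    no_capture = vapply(res, function(r) r$no_capture, logical(1))
  )
  attr(out, "config") <- config
  class(out) <- c("strength_duration_curve", "data.frame")
  out
}

apd_from_trace <- function(t, v, frac) {
  # activation at maximum dV/dt; APD until repolarization to
  # baseline + (1 - frac) of the amplitude
  dvdt <- diff(v) / diff(t)
  i_act <- which.max(dvdt)
  baseline <- v[1]
  i_peak <- i_act - 1 + which.max(v[i_act:length(v)])
  level <- baseline + (1 - frac) * (v[i_peak] - baseline)
  idx <- which(seq_along(v) > i_peak & v <= level)
  if (length(idx) == 0) return(NA_real_)
  t[idx[1]] - t[i_act]
}

#' Sensor-mode coupling metrics (ideal voltage indicator in the non-myocyte)
#'
#' Simulates a host cardiomyocyte / fibroblast pair (no ChR2), paces the
#' myocyte electrically to a quasi-steady state, and reports the metrics an
#' ideal genetically-encoded voltage indicator in the non-myocyte would
#' provide: the peak-to-trough voltage excursion of the non-myocyte over
#' one pacing cycle, and APD90/APD50 of both cells.
#'
#' @param g_gj gap-junctional conductance, nS
#' @param g_kv_scale fibroblast Kv conductance scale
#' @param pacing electrical pacing of the myocyte (default 72 pA/pF, 2 ms,
#'   1 Hz)
#' @param n_beats number of pacing cycles before measurement
#' @param settle quiescent coupling time before pacing, ms
#' @param record_dt trace sampling, ms
#' @return list with `amplitude_ncm`, `amplitude_cm` (mV), `apd90_cm`,
#'   `apd50_cm`, `apd90_ncm`, `apd50_ncm` (ms) and the measured `trace`
#' @export
sensor_mode_metrics <- function(g_gj = 1, g_kv_scale = 1,
                                pacing = stimulus_protocol(
                                  "electrical", 72, 2, period = 1000,
                                  n_pulses = 10, onset = 50),
                                n_beats = pacing$n_pulses, settle = 50e3,
                                record_dt = 0.5) {
  config <- tcu_config(donor_type = "fibroblast", n_fb = 1, g_gj = g_gj,
                       g_kv_scale = g_kv_scale, chr2 = FALSE)
  st0 <- default_tcu_states(config)
  pre <- run_tcu(config, st0, duration = settle, dt = config$dt_equil,
                 record_dt = settle)
  st <- res_states(config, pre, st0)

  period <- if (pacing$period > 0) pacing$period else 1000
  duration <- pacing$onset + n_beats * period
  tr <- simulate_tcu(config, st, pacing, duration, record_dt = record_dt)

  # last full cycle, from just before the last stimulus
  t_last <- pacing$onset + (n_beats - 1) * period
  cyc <- tr[tr$time >= t_last - 10 & tr$time < t_last + period - 10, ]
  amplitude_ncm <- max(cyc$v_donor_1) - min(cyc$v_donor_1)
  amplitude_cm <- max(cyc$v_host) - min(cyc$v_host)

  list(
    amplitude_ncm = amplitude_ncm,
    amplitude_cm = amplitude_cm,
    apd90_cm = apd_from_trace(cyc$time, cyc$v_host, 0.9),
    apd50_cm = apd_from_trace(cyc$time, cyc$v_host, 0.5),
    apd90_ncm = apd_from_trace(cyc$time, cyc$v_donor_1, 0.9),
    apd50_ncm = apd_from_trace(cyc$time, cyc$v_donor_1, 0.5),
    g_gj = g_gj,
    trace = cyc
  )
}
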