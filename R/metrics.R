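## Post-processing analytics: strength-duration (rheobase/chronaxie)
## fitting, the sigma sensitivity metric, and gapFRAP normalization and
## recovery fitting.

sd_model <- function(t, rheobase, chronaxie, variant) {
  k <- if (variant == "log2") log(2) else 1
  rheobase / (1 - exp(-t * k / chronaxie))
}

#' Fit a strength-duration curve (parallel-RC form)
#'
#' Fits `Irradiance = Rheobase / (1 - exp(-t / Chronaxie))` (variant
#' `"plain"`) or the half-time parameterization
#' `Rheobase / (1 - exp(-t log(2) / Chronaxie))` (variant `"log2"`) by
#' nonlinear least squares. Chronaxies from the two variants are
#' inter-convertible: `chronaxie_log2 = chronaxie_plain * log(2)`.
#'
#' @param curve a data.frame with columns `duration_ms` and
#'   `irradiance_mW_mm2` (a `strength_duration_curve` works directly;
#'   rows flagged `no_capture` are dropped)
#' @param variant `"plain"` or `"log2"`
#' @param tol least-squares convergence tolerance (ftol/ptol)
#' @param max_iter maximum number of optimizer iterations
#' @return an object of class `sd_fit`: `rheobase` (mW/mm^2), `chronaxie`
#'   (ms), `residual_norm`, `formula_variant`, `converged` and the
#'   underlying `fit`
#' @export
fit_strength_duration <- function(curve, variant = c("plain", "log2"),
                                  tol = 1e-12, max_iter = 1024) {
  variant <- match.arg(variant)
  if (!is.null(curve$no_capture)) curve <- curve[!curve$no_capture, ]
  t <- curve$duration_ms
  irr <- curve$irradiance_mW_mm2
  if (is.null(t) || is.null(irr)) {
    t <- curve[[1]]; irr <- curve[[2]]
  }
  keep <- is.finite(t) & is.finite(irr)
  t <- t[keep]; irr <- irr[keep]
  if (length(unique(t)) < 3) stop("need at least 3 distinct pulse durations")
  if (any(irr <= 0)) stop("irradiances must be positive")

  start <- list(rheobase = min(irr), chronaxie = stats::median(t))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      irr ~ sd_model(t, rheobase, chronaxie, variant),
      start = start,
      lower = c(1e-12, 1e-9),
      control = minpack.lm::nls.lm.control(
        maxiter = max_iter, ftol = tol, ptol = tol)),
    error = function(e) NULL)

  if (is.null(fit)) {
    return(structure(list(
      rheobase = NA_real_, chronaxie = NA_real_, residual_norm = NA_real_,
      formula_variant = variant, converged = FALSE, fit = NULL
    ), class = "sd_fit"))
  }
  cf <- stats::coef(fit)
  structure(list(
    rheobase = unname(cf["rheobase"]), chronaxie = unname(cf["chronaxie"]),
    residual_norm = sqrt(sum(stats::residuals(fit)^2)),
    formula_variant = variant, converged = TRUE, fit = fit
  ), class = "sd_fit")
}

#' @export
print.sd_fit <- function(x, ...) {
  cat(sprintf(
    "strength-duration fit (%s): rheobase = %.4g mW/mm^2, chronaxie = %.4g ms%s\n",
    x$formula_variant, x$rheobase, x$chronaxie,
    if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' OptoGap assay sensitivity metric
#'
#' `sigma = log10(E_e,th / E_e,th(G_gj,max))`. Values farther from 0 in
#' either direction indicate a more sensitive assay; by construction
#' `sigma = 0` at the reference maximal coupling (20 nS by convention).
#'
#' @param e excitation threshold(s), mW/mm^2 (positive)
#' @param e_max excitation threshold at maximal coupling, mW/mm^2
#' @return sigma (unitless, vectorized over `e`)
#' @export
sigma_metric <- function(e, e_max) {
  if (any(!is.finite(e)) || any(e <= 0) || !is.finite(e_max) || e_max <= 0)
    stop("thresholds must be positive and finite")
  log10(e / e_max)
}

#' Assay sensitivity across a coupling grid
#'
#' Runs [find_excitation_threshold()] for each gap-junctional conductance
#' in the grid (equilibrating each configuration), references the result to
#' `g_gj_max`, and flags non-monotonic (U-shaped) threshold-coupling
#' relationships, which invalidate the assay readout.
#'
#' @param config template [tcu_config()] (its `g_gj` is replaced)
#' @param g_gj_grid gap-junctional conductances, nS
#' @param pulse_duration optical pulse duration, ms
#' @param g_gj_max reference maximal coupling, nS (appended to the grid if
#'   absent)
#' @param ... passed to [find_excitation_threshold()]
#' @return a `sensitivity_curve` data.frame with columns `g_gj`, `e_th`,
#'   `sigma` and `no_capture`; attributes `e_max`, `u_shaped` and
#'   `monotone_decreasing`
#' @export
sensitivity_curve <- function(config, g_gj_grid = c(2, 5, 10, 15, 20),
                              pulse_duration = 50, g_gj_max = 20, ...) {
  grid <- sort(unique(c(g_gj_grid, g_gj_max)))
  e <- vapply(grid, function(g) {
    cfg <- config
    cfg$g_gj <- g
    find_excitation_threshold(cfg, pulse_duration = pulse_duration,
                              ...)$e_th
  }, numeric(1))
  e_max <- e[match(g_gj_max, grid)]
  sig <- ifelse(is.na(e) | e <= 0, NA_real_, log10(e / e_max))

  keep <- match(sort(unique(g_gj_grid)), grid)
  out <- data.frame(g_gj = grid[keep], e_th = e[keep], sigma = sig[keep],
                    no_capture = is.na(e[keep]))
  ok <- is.finite(e)
  eo <- e[ok]
  u_shaped <- FALSE
  if (length(eo) >= 3) {
    i_min <- which.min(eo)
    u_shaped <- i_min > 1 && i_min < length(eo) &&
      eo[1] > eo[i_min] * 1.02 && eo[length(eo)] > eo[i_min] * 1.02
  }
  attr(out, "e_max") <- e_max
  attr(out, "u_shaped") <- u_shaped
  attr(out, "monotone_decreasing") <- all(diff(eo) <= 1e-12 + 0.02 * eo[-1])
  class(out) <- c("sensitivity_curve", "data.frame")
  out
}

#' Normalize a gapFRAP fluorescence trace
#'
#' Normalizes raw intensities to the first post-bleach frame as zero:
#' `(F(t) - F(t0)) / F(t0) * 100`.
#'
#' @param time frame times, s
#' @param fluorescence raw mean intensities of the bleached region
#' @return data.frame `(time_s, f_norm)` with `f_norm[1] == 0`
#' @export
normalize_frap <- function(time, fluorescence) {
  stopifnot(length(time) == length(fluorescence), length(time) >= 1,
            fluorescence[1] != 0)
  data.frame(time_s = time,
             f_norm = (fluorescence - fluorescence[1]) / fluorescence[1] * 100)
}

#' Fit a gapFRAP recovery curve
#'
#' Fits the perturbation-relaxation form
#' `F(t) = F0 + (F_inf - F0) (1 - exp(-t / tau))` to a normalized recovery
#' trace and reports the time constant `tau` (s) and the derived rate
#' `Dn = 1/tau` (1/s), the coupling index used by the assay.
#'
#' @param trace data.frame with columns `time_s` and `f_norm` (as returned
#'   by [normalize_frap()]); at least 5 time points
#' @param tol least-squares convergence tolerance
#' @param max_iter maximum optimizer iterations
#' @return an object of class `frap_fit`: `f0`, `f_inf`, `tau` (s),
#'   `dn` (1/s), `residual_norm`, `converged`
#' @export
fit_frap_recovery <- function(trace, tol = 1e-12, max_iter = 1024) {
  t <- trace$time_s
  f <- trace$f_norm
  if (is.null(t) || is.null(f)) {
    t <- trace[[1]]; f <- trace[[2]]
  }
  stopifnot(length(t) >= 5)

  not_converged <- structure(list(
    f0 = NA_real_, f_inf = NA_real_, tau = NA_real_, dn = NA_real_,
    residual_norm = NA_real_, converged = FALSE, fit = NULL
  ), class = "frap_fit")

  span <- max(f) - min(f)
  if (!is.finite(span) || span < 1e-8) return(not_converged)  # flat trace

  # deterministic starts: tau0 from a log-linear regression of the
  # remaining recovery, F0/Finf from the trace ends
  f0_0 <- f[1]
  finf_0 <- max(f) + 0.05 * span
  resid <- finf_0 - f
  pos <- resid > 0
  tau0 <- if (sum(pos) >= 2) {
    sl <- unname(stats::coef(stats::lm(log(resid[pos]) ~ t[pos]))[2])
    if (is.finite(sl) && sl < 0) -1 / sl else diff(range(t)) / 3
  } else diff(range(t)) / 3

  fit <- tryCatch(
    minpack.lm::nlsLM(
      f ~ f0 + (f_inf - f0) * (1 - exp(-t / tau)),
      start = list(f0 = f0_0, f_inf = finf_0, tau = tau0),
      lower = c(-Inf, -Inf, 1e-9),
      control = minpack.lm::nls.lm.control(
        maxiter = max_iter, ftol = tol, ptol = tol)),
    error = function(e) NULL)
  if (is.null(fit)) return(not_converged)

  cf <- stats::coef(fit)
  structure(list(
    f0 = unname(cf["f0"]), f_inf = unname(cf["f_inf"]),
    tau = unname(cf["tau"]), dn = 1 / unname(cf["tau"]),
    residual_norm = sqrt(sum(stats::residuals(fit)^2)),
    converged = TRUE, fit = fit
  ), class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  if (!x$converged) {
    cat("gapFRAP fit: not converged (non-recovering trace?)\n")
  } else {
    cat(sprintf(
      "gapFRAP fit: tau = %.4g s, Dn = 1/tau = %.4g 1/s (F0 = %.3g, F_inf = %.3g)\n",
      x$tau, x$dn, x$f0, x$f_inf))
  }
  invisible(x)
}
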