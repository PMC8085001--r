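## Synthetic-data generators for the two measured-curve inputs the assay
## analyses: strength-duration tables and gapFRAP recovery traces.

#' Generate a synthetic strength-duration curve
#'
#' Samples the parallel-RC strength-duration form
#' `Irradiance = Rheobase / (1 - exp(-t / Chronaxie))` at the given pulse
#' durations, with optional multiplicative Gaussian noise (the measurement
#' noise of threshold irradiances is proportional to their magnitude).
#' The defaults emulate a control-coupling preparation: rheobase
#' 0.02 mW/mm^2 and chronaxie 15 ms, which spans thresholds of roughly
#' 0.02-0.16 mW/mm^2 over 2-100 ms pulses.
#'
#' @param rheobase asymptotic threshold, mW/mm^2
#' @param chronaxie duration constant, ms
#' @param durations pulse durations, ms (>= 3 values)
#' @param noise_cv coefficient of variation of the multiplicative noise
#' @param seed integer RNG seed (`NULL` = leave the RNG stream alone)
#' @param variant `"plain"` or `"log2"` strength-duration form
#' @return a `strength_duration_curve` data.frame `(duration_ms,
#'   irradiance_mW_mm2)` with the true parameters in attribute `"truth"`
#' @export
generate_synthetic_sd <- function(rheobase = 0.02, chronaxie = 15,
                                  durations = c(2, 5, 10, 20, 50, 100),
                                  noise_cv = 0.05, seed = NULL,
                                  variant = c("plain", "log2")) {
  variant <- match.arg(variant)
  stopifnot(rheobase > 0, chronaxie > 0, length(durations) >= 3,
            noise_cv >= 0)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()),
              add = TRUE)
    }
    set.seed(seed)
  }
  irr <- sd_model(durations, rheobase, chronaxie, variant)
  if (noise_cv > 0)
    irr <- irr * (1 + stats::rnorm(length(irr), sd = noise_cv))
  out <- data.frame(duration_ms = durations, irradiance_mW_mm2 = irr)
  attr(out, "truth") <- list(rheobase = rheobase, chronaxie = chronaxie,
                             variant = variant, noise_cv = noise_cv,
                             seed = seed)
  class(out) <- c("strength_duration_curve", "data.frame")
  out
}

#' Generate a synthetic gapFRAP recovery trace
#'
#' Samples the mono-exponential recovery
#' `F(t) = F0 + (F_inf - F0)(1 - exp(-t / tau))` on the standard imaging
#' grid (a frame every 5 s for 195 s), with optional additive Gaussian
#' noise in normalized-fluorescence units.
#'
#' @param f0 normalized fluorescence at the first post-bleach frame
#' @param f_inf recovery plateau (normalized units)
#' @param tau recovery time constant, s
#' @param times frame times, s
#' @param noise_sd additive noise standard deviation (normalized units)
#' @param seed integer RNG seed (`NULL` = leave the RNG stream alone)
#' @return a data.frame `(time_s, f_norm)` with the true parameters in
#'   attribute `"truth"`
#' @export
generate_synthetic_frap <- function(f0 = 0, f_inf = 40, tau = 50,
                                    times = seq(0, 195, by = 5),
                                    noise_sd = 0, seed = NULL) {
  stopifnot(tau > 0, f_inf >= f0, length(times) >= 5, noise_sd >= 0)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()),
              add = TRUE)
    }
    set.seed(seed)
  }
  f <- f0 + (f_inf - f0) * (1 - exp(-times / tau))
  if (noise_sd > 0) f <- f + stats::rnorm(length(f), sd = noise_sd)
  out <- data.frame(time_s = times, f_norm = f)
  attr(out, "truth") <- list(f0 = f0, f_inf = f_inf, tau = tau,
                             noise_sd = noise_sd, seed = seed)
  out
}
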