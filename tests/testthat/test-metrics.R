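# Strength-duration fitting, sigma metric, gapFRAP fitting

test_that("noiseless strength-duration data are recovered exactly", {
  for (variant in c("plain", "log2")) {
    curve <- generate_synthetic_sd(rheobase = 0.02, chronaxie = 15,
                                   noise_cv = 0, variant = variant)
    fit <- fit_strength_duration(curve, variant = variant)
    expect_true(fit$converged)
    expect_rel_equal(fit$rheobase, 0.02, 1e-6)
    expect_rel_equal(fit$chronaxie, 15, 1e-6)
  }
})

test_that("fitted curve asymptotes to the rheobase at long durations", {
  curve <- generate_synthetic_sd(rheobase = 0.05, chronaxie = 10,
                                 durations = c(3, 8, 20, 60, 200, 1000),
                                 noise_cv = 0)
  fit <- fit_strength_duration(curve)
  pred <- fit$rheobase / (1 - exp(-5000 / fit$chronaxie))
  expect_rel_equal(pred, fit$rheobase, 1e-10)
  expect_rel_equal(curve$irradiance_mW_mm2[6], 0.05, 1e-3)
})

test_that("chronaxies from the two formula variants differ by log(2)", {
  curve <- generate_synthetic_sd(rheobase = 0.03, chronaxie = 12,
                                 noise_cv = 0.03, seed = 11)
  f_plain <- fit_strength_duration(curve, "plain")
  f_log2 <- fit_strength_duration(curve, "log2")
  expect_rel_equal(f_log2$chronaxie, f_plain$chronaxie * log(2), 1e-6)
  expect_rel_equal(f_log2$rheobase, f_plain$rheobase, 1e-6)
})

test_that("noisy strength-duration fits recover parameters within 10%", {
  errs <- t(vapply(1:100, function(s) {
    curve <- generate_synthetic_sd(rheobase = 0.02, chronaxie = 15,
                                   noise_cv = 0.05, seed = s)
    fit <- fit_strength_duration(curve)
    c(abs(fit$rheobase - 0.02) / 0.02, abs(fit$chronaxie - 15) / 15)
  }, numeric(2)))
  expect_lt(median(errs[, 1]), 0.1)
  expect_lt(median(errs[, 2]), 0.1)
})

test_that("strength-duration fitting validates its input", {
  expect_error(fit_strength_duration(
    data.frame(duration_ms = c(5, 5, 5), irradiance_mW_mm2 = c(1, 1, 1))),
    "distinct")
  expect_error(fit_strength_duration(
    data.frame(duration_ms = c(2, 5, 10), irradiance_mW_mm2 = c(1, -1, 1))),
    "positive")
})

test_that("sigma metric matches the printed examples and rejects bad input", {
  expect_identical(sigma_metric(0.5, 0.5), 0)
  expect_equal(sigma_metric(2.45, 0.13), 1.28, tolerance = 0.01)
  expect_equal(sigma_metric(0.47, 0.09), 0.72, tolerance = 0.01)
  expect_equal(sigma_metric(c(1, 10, 0.1), 1), c(0, 1, -1))
  expect_error(sigma_metric(-1, 0.5), "positive")
  expect_error(sigma_metric(0.5, 0), "positive")
})

test_that("frap normalization anchors the first post-bleach frame at zero", {
  t <- seq(0, 50, 5)
  flat <- normalize_frap(t, rep(300, length(t)))
  expect_true(all(flat$f_norm == 0))
  tr <- normalize_frap(c(0, 5, 10), c(200, 300, 400))
  expect_identical(tr$f_norm[1], 0)
  expect_identical(tr$f_norm[3], 100)  # doubling from F(t0)
  # linear in raw intensities about F(t0)
  a <- normalize_frap(t, 100 + t)$f_norm
  b <- normalize_frap(t, 2 * (100 + t))$f_norm
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("noiseless FRAP recovery is fit exactly and Dn = 1/tau", {
  tr <- generate_synthetic_frap(f0 = 0, f_inf = 40, tau = 50, noise_sd = 0)
  fit <- fit_frap_recovery(tr)
  expect_true(fit$converged)
  expect_rel_equal(fit$tau, 50, 1e-6)
  expect_rel_equal(fit$f_inf, 40, 1e-6)
  expect_equal(fit$dn, 1 / fit$tau)
  # the printed low-coupling diffusion rate corresponds to tau = 1/0.014
  tr2 <- generate_synthetic_frap(tau = 1 / 0.014, noise_sd = 0)
  fit2 <- fit_frap_recovery(tr2)
  expect_equal(fit2$dn, 0.014, tolerance = 1e-6)
})

test_that("noisy FRAP fits recover tau within 10% and are unbiased", {
  errs <- vapply(1:100, function(s) {
    tr <- generate_synthetic_frap(f0 = 0, f_inf = 40, tau = 50,
                                  noise_sd = 2, seed = s)
    fit_frap_recovery(tr)$tau
  }, numeric(1))
  expect_lt(median(abs(errs - 50) / 50), 0.1)
  # bias shrinks with the noise level
  small <- vapply(1:100, function(s) {
    tr <- generate_synthetic_frap(f0 = 0, f_inf = 40, tau = 50,
                                  noise_sd = 0.2, seed = s)
    fit_frap_recovery(tr)$tau
  }, numeric(1))
  expect_lt(abs(mean(small) - 50), abs(mean(errs) - 50) + 0.5)
  expect_lt(abs(mean(small) - 50) / 50, 0.02)
})

test_that("non-recovering traces are flagged, not silently fit", {
  flat <- data.frame(time_s = seq(0, 100, 5), f_norm = rep(0, 21))
  fit <- fit_frap_recovery(flat)
  expect_false(fit$converged)
  expect_true(is.na(fit$tau))
})

test_that("synthetic generators are seed-reproducible", {
  a <- generate_synthetic_sd(noise_cv = 0.05, seed = 3)
  b <- generate_synthetic_sd(noise_cv = 0.05, seed = 3)
  expect_identical(a$irradiance_mW_mm2, b$irradiance_mW_mm2)
  d <- generate_synthetic_frap(noise_sd = 2, seed = 9)
  e <- generate_synthetic_frap(noise_sd = 2, seed = 9)
  expect_identical(d$f_norm, e$f_norm)
  # and do not disturb the caller's RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(generate_synthetic_sd(noise_cv = 0.05, seed = 4))
  expect_identical(runif(1), before)
})

test_that("tabular IO round-trips losslessly", {
  curve <- generate_synthetic_sd(noise_cv = 0.05, seed = 2)
  f <- tempfile(fileext = ".csv")
  write_sd_curve(curve, f)
  back <- read_sd_curve(f)
  expect_equal(back$irradiance_mW_mm2, curve$irradiance_mW_mm2,
               tolerance = 1e-12)
  tr <- generate_synthetic_frap(noise_sd = 1, seed = 5)
  f2 <- tempfile(fileext = ".csv")
  write_frap_trace(tr, f2)
  back2 <- read_frap_trace(f2)
  expect_equal(back2$f_norm, tr$f_norm, tolerance = 1e-12)
  unlink(c(f, f2))
})
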