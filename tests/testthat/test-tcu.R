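# Tandem-cell-unit engine

test_that("junctional current vanishes at equal potentials and is antisymmetric", {
  cfg <- fast_fib_config(g_gj = 5)
  st <- optogap:::default_tcu_states(cfg)
  st$donors[, "V"] <- st$host[["V"]]  # equalize potentials
  tr <- simulate_tcu(cfg, st, NULL, duration = 1, record_dt = 0.02)
  expect_equal(tr$i_gj[1], 0, tolerance = 1e-12)
  # antisymmetry: the host receives exactly G_gj * sum(Vd - Vh); rebuild
  # the per-donor currents from the recorded potentials
  st2 <- equilibrate_fast(cfg, 5e3)
  tr2 <- simulate_tcu(cfg, st2,
                      stimulus_protocol("optical", 1, 10, onset = 5),
                      duration = 60, record_dt = 0.2)
  vd <- as.matrix(tr2[, grep("^v_donor_", names(tr2))])
  recon <- rowSums(cfg$g_gj * (vd - tr2$v_host))
  expect_lt(max(abs(recon - tr2$i_gj)), 1e-9)
})

test_that("zero-irradiance optical stimulation is a no-op", {
  cfg <- fast_fib_config()
  st <- equilibrate_fast(cfg, 5e3)
  quiet <- simulate_tcu(cfg, st, NULL, duration = 200, record_dt = 0.5)
  dark <- simulate_tcu(cfg, st, stimulus_protocol("optical", 0, 10, onset = 5),
                       duration = 200, record_dt = 0.5)
  expect_identical(quiet$v_host, dark$v_host)
  expect_identical(quiet$v_donor_1, dark$v_donor_1)
})

test_that("supra-threshold light on ChR2 fibroblasts triggers a host AP", {
  cfg <- fast_fib_config(g_gj = 10)
  st <- equilibrate_fast(cfg)
  tr <- simulate_tcu(cfg, st, stimulus_protocol("optical", 5, 50, onset = 10),
                     duration = 400, record_dt = 0.2)
  det <- detect_action_potential(tr, window = c(10, 400))
  expect_true(det$detected)
  expect_gt(max(tr$v_host), 10)
})

test_that("AP detection applies both the crossing and upstroke criteria", {
  t <- seq(0, 400, 0.5)
  flat <- data.frame(time = t, v_host = rep(-85, length(t)))
  expect_false(detect_action_potential(flat)$detected)
  sub <- data.frame(time = t, v_host = -85 + 45 * exp(-(t - 200)^2 / 2000))
  expect_false(detect_action_potential(sub)$detected)  # peaks at -40 mV
  # slow drift across 0 mV without a regenerative upstroke is rejected
  slow <- data.frame(time = t, v_host = -85 + 0.25 * t)
  expect_false(detect_action_potential(slow)$detected)
  # a paced host AP is detected
  paced <- simulate_tcu(fast_fib_config(),
                        optogap:::default_tcu_states(fast_fib_config()),
                        stimulus_protocol("electrical", 72, 2, onset = 20),
                        duration = 300, record_dt = 0.2)
  expect_true(detect_action_potential(paced, window = c(0, 300))$detected)
})

test_that("equilibration reaches quiescence and the decoupled limit", {
  cfg <- fast_fib_config(g_gj = 1e-6)
  st <- equilibrate_fast(cfg, duration = 60e3)
  expect_false(st$autorhythmic)
  expect_lt(st$max_dvdt, 1e-4)
  expect_lt(abs(st$v_rest_donor[1] - (-49.6)), 1.5)  # uncoupled fibroblast
  expect_lt(abs(st$v_rest_host - (-86.2)), 1)        # uncoupled host
  # coupled: fibroblasts hyperpolarize toward the host
  stc <- equilibrate_fast(fast_fib_config(g_gj = 5), duration = 60e3)
  expect_lt(stc$v_rest_donor[1], -65)
  expect_true(all(abs(stc$v_rest_donor - stc$v_rest_donor[1]) < 1e-9))
})

test_that("threshold bisection is deterministic and bracketed", {
  cfg <- fast_fib_config(g_gj = 10)
  st <- equilibrate_fast(cfg)
  th1 <- find_excitation_threshold(cfg, 20, states = st)
  th2 <- find_excitation_threshold(cfg, 20, states = st)
  expect_identical(th1$e_th, th2$e_th)  # bit-identical rerun
  expect_false(th1$no_capture)
  expect_false(th1$detect_low$detected)   # no AP just below
  expect_true(th1$detect_high$detected)   # AP at the returned threshold
  expect_lte(th1$bracket[2] - th1$bracket[1], 0.01 * th1$e_th + 1e-12)
})

test_that("bisection agrees with an exhaustive grid scan", {
  # oracle: march a uniform grid of step rel_tol * E upward from below
  # the bisection bracket and take the first capturing irradiance
  configs <- list(
    list(g = 4, d = 20), list(g = 6, d = 20), list(g = 8, d = 20),
    list(g = 10, d = 20), list(g = 14, d = 20), list(g = 20, d = 20),
    list(g = 6, d = 50), list(g = 10, d = 50), list(g = 14, d = 10),
    list(g = 20, d = 10))
  for (cs in configs) {
    cfg <- fast_fib_config(g_gj = cs$g)
    st <- equilibrate_fast(cfg)
    th <- find_excitation_threshold(cfg, cs$d, states = st, rel_tol = 0.05)
    expect_false(th$no_capture)
    step <- 0.05 * th$e_th
    grid <- seq(max(th$e_th - 5 * step, step / 2), th$e_th + 2 * step,
                by = step)
    fires <- vapply(grid, function(e) {
      tr <- simulate_tcu(cfg, st, stimulus_protocol("optical", e, cs$d,
                                                    onset = 10),
                         duration = 520, record_dt = 0.2)
      detect_action_potential(tr, window = c(10, 510))$detected
    }, logical(1))
    first <- grid[which(fires)[1]]
    # grid-scan first capture lies within one grid step of the bisection
    expect_lt(abs(first - th$e_th), step + 1e-12)
    # and capture is monotone along the grid (single transition)
    expect_true(all(diff(fires) >= 0))
  }
})

test_that("strength-duration scan reuses states and is ordered in coupling", {
  cfg2 <- fast_fib_config(g_gj = 4)
  cfg10 <- fast_fib_config(g_gj = 10)
  st2 <- equilibrate_fast(cfg2)
  st10 <- equilibrate_fast(cfg10)
  durs <- c(10, 20, 50)
  sd2 <- strength_duration_scan(cfg2, durs, states = st2)
  sd10 <- strength_duration_scan(cfg10, durs, states = st10)
  expect_s3_class(sd2, "strength_duration_curve")
  # threshold decreases (or is flat) with pulse duration
  expect_true(all(diff(sd2$irradiance_mW_mm2) <= 1e-12 +
                    0.02 * sd2$irradiance_mW_mm2[-1]))
  # the higher-coupling curve lies at-or-below the low-coupling curve
  expect_true(all(sd10$irradiance_mW_mm2 <=
                    sd2$irradiance_mW_mm2 * 1.02))
  # single-duration scan reduces to find_excitation_threshold
  one <- strength_duration_scan(cfg10, 20, states = st10)
  th <- find_excitation_threshold(cfg10, 20, states = st10)
  expect_equal(one$irradiance_mW_mm2, th$e_th)
})

test_that("sensor-mode metrics scale with coupling and report APDs", {
  m0 <- sensor_mode_metrics(g_gj = 0, settle = 10e3, n_beats = 4)
  expect_lt(m0$amplitude_ncm, 0.01)
  m1 <- sensor_mode_metrics(g_gj = 1, settle = 10e3, n_beats = 4)
  m3 <- sensor_mode_metrics(g_gj = 3, settle = 10e3, n_beats = 4)
  expect_gt(m1$amplitude_ncm, 20)
  expect_gt(m3$amplitude_ncm, m1$amplitude_ncm)  # monotone in coupling
  expect_gt(m1$apd90_cm, m1$apd50_cm)
  expect_lt(m3$apd90_cm, m1$apd90_cm)  # fibroblast loading shortens APD
})
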