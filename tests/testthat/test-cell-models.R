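# Single-cell ionic models

test_that("fibroblast with all conductances zeroed is inert", {
  p <- fibroblast_params(g_Kv = 0, g_K1 = 0, g_bNa = 0, i_NaK_max = 0)
  dy <- fibroblast_rhs(fibroblast_state(), i_in = 0, params = p)
  expect_equal(dy[["V"]], 0, tolerance = 1e-12)
})

test_that("uncoupled fibroblast rests depolarized relative to the host CM", {
  fib <- simulate_cell("fibroblast", duration = 20e3, record_dt = 10)
  host <- simulate_cell("myocyte", duration = 20e3, fix_nak = TRUE,
                        record_dt = 10)
  v_fib <- tail(fib$v, 1)
  v_host <- tail(host$v, 1)
  expect_gt(v_fib, v_host + 20)          # the premise behind coupling-
  expect_lt(abs(v_fib - (-49.6)), 1.5)   # induced cFB hyperpolarization
})

test_that("Kv conductance scaling shifts the fibroblast resting potential", {
  rest <- function(scale) {
    tr <- simulate_cell("fibroblast", duration = 30e3,
                        params = fibroblast_params(g_Kv_scale = scale),
                        record_dt = 100)
    tail(tr$v, 1)
  }
  v_half <- rest(0.5); v_def <- rest(1); v_dbl <- rest(2)
  expect_gt(v_half, v_def)  # halving g_Kv depolarizes
  expect_lt(v_dbl, v_def)   # doubling hyperpolarizes
})

test_that("host CM holds a stable resting potential near the published value", {
  tr <- simulate_cell("myocyte", duration = 5000, fix_nak = TRUE,
                      record_dt = 10)
  expect_lt(abs(tail(tr$v, 1) - (-86.2)), 1)
  dvdt <- diff(tail(tr$v, 100)) / 10
  expect_lt(max(abs(dvdt)), 1e-4)
})

test_that("removing fast Na+ abolishes the regenerative upstroke", {
  stim <- stimulus_protocol("electrical", 72, 2, onset = 50)
  full <- simulate_cell("myocyte", duration = 500, electrical = stim,
                        record_dt = 0.2)
  none <- simulate_cell("myocyte", duration = 500, electrical = stim,
                        params = myocyte_params(ina_fraction = 0),
                        record_dt = 0.2)
  peak_dvdt <- function(tr) max(diff(tr$v) / 0.2)
  expect_gt(peak_dvdt(full), 2 * peak_dvdt(none))
  expect_gt(peak_dvdt(full), 150)   # regenerative fast upstroke
  expect_lt(peak_dvdt(none), 100)   # stimulus artefact only
})

test_that("scale_ina scales only the fast Na+ conductance", {
  p <- myocyte_params()
  expect_identical(scale_ina(p, 1), p)
  p0 <- scale_ina(p, 0)
  expect_equal(p0$g_Na, 0)
  p5 <- scale_ina(p, 0.5)
  expect_equal(p5$g_Na, p$g_Na / 2)
  expect_equal(p5$g_K1, p$g_K1)
  q <- ipsc_cm_params()
  expect_equal(scale_ina(q, 0.25)$g_Na, q$g_Na / 4)
  expect_error(scale_ina(p, 1.5))
  # the compiled path honours the scaling: INa term halves
  y <- myocyte_state(); y[["V"]] <- -30; y[["m"]] <- 0.9
  y[["h"]] <- 0.5; y[["j"]] <- 0.5
  d1 <- host_cm_rhs(y, params = myocyte_params(ina_fraction = 1))[["V"]]
  d5 <- host_cm_rhs(y, params = myocyte_params(ina_fraction = 0.5))[["V"]]
  d0 <- host_cm_rhs(y, params = myocyte_params(ina_fraction = 0))[["V"]]
  expect_equal(d5, (d1 + d0) / 2, tolerance = 1e-10)
})

test_that("donor hiPSC-CM is spontaneously active with sensible morphology", {
  tr <- simulate_cell("ipsc_cm", duration = 10e3, record_dt = 1)
  upstrokes <- sum(diff(sign(tr$v)) > 0)
  expect_gte(upstrokes, 2)            # spontaneous beating
  expect_gt(max(tr$v), 10)            # overshooting APs
  expect_lt(min(tr$v), -65)           # diastolic potential
})

test_that("gating variables stay within [0, 1] along trajectories", {
  stim <- stimulus_protocol("electrical", 72, 2, period = 500,
                            n_pulses = 3, onset = 20)
  tr <- simulate_cell("myocyte", duration = 1600, electrical = stim,
                      record_dt = 1)
  fin <- attr(tr, "final")
  gates <- fin[c("m", "h", "j", "d", "f", "r", "s", "xs", "xr1", "xr2", "g")]
  expect_true(all(gates >= 0 & gates <= 1))
  trp <- simulate_cell("ipsc_cm", duration = 5000, record_dt = 1)
  finp <- attr(trp, "final")
  gp <- finp[c("m", "h", "j", "d", "f1", "f2", "Xr1", "Xr2", "Xs", "Xf",
               "q", "r", "g")]
  expect_true(all(gp >= 0 & gp <= 1))
})

test_that("compiled fixed-step integration agrees with an adaptive solver", {
  skip_if_not_installed("deSolve")
  # the compiled Rush-Larsen/Euler path is checked against lsoda driving
  # the same right-hand side (host relaxing from the published initial
  # conditions, and the fibroblast with a small depolarizing current)
  y0 <- unname(myocyte_state())
  ref <- deSolve::lsoda(y0, seq(0, 400, 1), function(t, y, p)
    list(optogap:::tnnp_rhs_cpp(y, 0, 0, 1)), NULL,
    rtol = 1e-8, atol = 1e-8)
  mine <- simulate_cell("myocyte", duration = 400, record_dt = 1)
  expect_lt(max(abs(mine$v - ref[, 2])), 0.05)

  pf <- fibroblast_params()
  yf <- unname(fibroblast_state())
  reff <- deSolve::lsoda(yf, seq(0, 500, 1), function(t, y, p)
    list(optogap:::fib_rhs_cpp(y, optogap:::as_fib_vec(pf), 0.5)), NULL,
    rtol = 1e-8, atol = 1e-8)
  minef <- simulate_cell("fibroblast", duration = 500, record_dt = 1,
    electrical = stimulus_protocol("electrical", 0.5, 500, onset = 0))
  expect_lt(max(abs(minef$v - reff[, 2])), 0.05)
})
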