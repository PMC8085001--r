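# ChR2 photocycle and photocurrent

test_that("rectification factor matches its closed form", {
  p <- chr2_params()
  # root of a - b exp(-V/c)
  v_root <- -p$rect_c * log(p$rect_a / p$rect_b)
  expect_equal(eval_rectification(v_root), 0, tolerance = 1e-10)
  expect_equal(v_root, 13.66, tolerance = 1e-2)
  # direct evaluation at -80 mV
  expect_equal(eval_rectification(-80),
               10.64 - 14.64 * exp(80 / 42.77), tolerance = 1e-12)
  expect_lt(abs(eval_rectification(-80) - (-84.4)), 0.1)
  # asymptote for depolarized potentials
  expect_equal(eval_rectification(1e4), p$rect_a, tolerance = 1e-6)
  # the divided-by-Vm variant with zero reversal coincides with the
  # printed form away from Vm = 0
  pd <- chr2_params(variant = "divided")
  st <- chr2_state(); st[["O1"]] <- 0.5; st[["C1"]] <- 0.5
  for (v in c(-90, -40, 5, 30))
    expect_equal(chr2_current(st, v, pd), chr2_current(st, v, chr2_params()),
                 tolerance = 1e-10)
})

test_that("photocurrent is the occupancy-weighted rectified conductance", {
  p <- chr2_params()
  st <- chr2_state()
  expect_identical(chr2_current(st, -80, p), 0)  # all channels closed
  st1 <- st; st1[["O1"]] <- 1; st1[["C1"]] <- 0
  i1 <- chr2_current(st1, -80, p)
  expect_equal(i1, 0.4 * eval_rectification(-80), tolerance = 1e-12)
  expect_lt(abs(i1 - (-33.8)), 0.1)
  expect_lt(i1, 0)  # inward below reversal
  # linearity in gamma: O2-only current is gamma times the O1-only current
  st2 <- st; st2[["O2"]] <- 1; st2[["C1"]] <- 0
  expect_equal(chr2_current(st2, -80, p), p$gamma * i1, tolerance = 1e-12)
  # linearity in (O1 + gamma O2) at fixed Vm
  mix <- st; mix[["O1"]] <- 0.3; mix[["O2"]] <- 0.4; mix[["C1"]] <- 0.3
  expect_equal(chr2_current(mix, -55, p),
               (0.3 + p$gamma * 0.4) * chr2_current(st1, -55, p),
               tolerance = 1e-12)
})

test_that("photocycle derivatives conserve occupancy and reject bad input", {
  p <- chr2_params()
  expect_error(chr2_rhs(chr2_state(), -1, -70), "non-negative")
  # dark steady state: all channels in C1
  dy <- chr2_rhs(chr2_state(), 0, -70, p)
  expect_equal(max(abs(dy[c("O1", "O2", "C1", "C2")])), 0, tolerance = 1e-12)
  # conservation for arbitrary states and light levels
  set.seed(42)
  for (i in 1:25) {
    occ <- stats::runif(4); occ <- occ / sum(occ)
    st <- c(O1 = occ[1], O2 = occ[2], C1 = occ[3], C2 = occ[4],
            p = stats::runif(1))
    dy <- chr2_rhs(st, stats::runif(1, 0, 50), stats::runif(1, -90, 30), p)
    expect_lt(abs(sum(dy[c("O1", "O2", "C1", "C2")])), 1e-12)
  }
})

test_that("long-run occupancies match the rate-matrix null space", {
  p <- chr2_params()
  for (case in list(c(-70, 0.5), c(-70, 5), c(-30, 1), c(-85, 20))) {
    vm <- case[1]; irr <- case[2]
    truth <- chr2_steady_oracle(vm, irr, p)
    y <- optogap:::chr2_run_cpp(unname(chr2_state()), optogap:::as_chr2_vec(p),
                                vm, irr, 60e3, 0.02)
    expect_equal(y[1:4], truth, tolerance = 2e-3)
    expect_equal(sum(y[1:4]), 1, tolerance = 1e-6)
  }
})

test_that("occupancies stay conserved and bounded along a driven trajectory", {
  p <- chr2_params()
  y <- unname(chr2_state())
  for (irr in c(0, 2, 0, 80, 0)) {
    y <- optogap:::chr2_run_cpp(y, optogap:::as_chr2_vec(p), -60, irr, 40, 0.02)
    expect_equal(sum(y[1:4]), 1, tolerance = 1e-6)
    expect_true(all(y[1:4] >= -1e-9 & y[1:4] <= 1 + 1e-9))
  }
})

test_that("a dark ChR2 block leaves the carrying cell unchanged", {
  plain <- simulate_cell("fibroblast", duration = 2000, record_dt = 1)
  dark <- simulate_cell("fibroblast", duration = 2000, record_dt = 1,
                        chr2 = chr2_params())
  expect_lt(max(abs(plain$v - dark$v)), 1e-9)
})
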