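# Shared helpers: independent oracles and scaled-down configurations.

# Independent transcription of the four-state photocycle rate matrix for the
# open/closed occupancies (O1, O2, C1, C2) at clamped membrane potential and
# irradiance, built directly from the published rate expressions. Used as a
# linear-algebra oracle for the integrated photocycle; kept separate from the
# package's compiled right-hand side.
chr2_rate_matrix_oracle <- function(vm, irr, p = chr2_params()) {
  f_act <- p$flux_factor * irr
  s0 <- 0.5 * (1 + tanh(120 * (p$theta_scale * irr - 0.1)))
  k1 <- p$eps1 * f_act * s0   # adaptation variable at its fixed point
  k2 <- p$eps2 * f_act * s0
  gd1 <- 0.075 + 0.043 * tanh(-(vm + 20) / 20)
  gd2 <- 0.05
  gr <- 4.34587e-5 * exp(-0.0211539274 * vm)
  e12 <- p$e12_dark + p$c1 * log(1 + irr / p$i_half)
  e21 <- p$e21_dark + p$c2 * log(1 + irr / p$i_half)
  # columns/rows: O1, O2, C1, C2
  matrix(c(
    -(gd1 + e12), e21,           k1,  0,
    e12,          -(gd2 + e21),  0,   k2,
    gd1,          0,             -k1, gr,
    0,            gd2,           0,   -(k2 + gr)
  ), nrow = 4, byrow = TRUE)
}

# steady-state occupancies: null space of the rate matrix + conservation
chr2_steady_oracle <- function(vm, irr, p = chr2_params()) {
  a <- chr2_rate_matrix_oracle(vm, irr, p)
  m <- rbind(a[1:3, ], rep(1, 4))
  as.numeric(solve(m, c(0, 0, 0, 1)))
}

# fast TCU test fixtures: short equilibration, coarse tolerance
fast_fib_config <- function(g_gj = 5, ...) {
  tcu_config("fibroblast", n_fb = 5, g_gj = g_gj, ...)
}

equilibrate_fast <- function(config, duration = 20e3) {
  suppressWarnings(equilibrate_tcu(config, duration = duration))
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}
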