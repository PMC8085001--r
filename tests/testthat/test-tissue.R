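# Monodomain tissue model, donor placement, light field

small_grid <- function() tissue_grid(width = 5, height = 5, spacing = 0.2,
                                     d_diff = 0.1, region_radius = 1.5)

test_that("placement density is exact, deterministic, and region-bound", {
  g <- small_grid()
  p <- place_donor_cells(g, density = 0.25, clustering = 0.9, seed = 5)
  expect_identical(length(p$occupied), p$n_target)
  expect_identical(p$n_target,
                   as.integer(ceiling(0.25 * sum(g$region))))
  expect_true(all(g$region[p$occupied]))
  p2 <- place_donor_cells(g, density = 0.25, clustering = 0.9, seed = 5)
  expect_identical(p$occupied, p2$occupied)
  # full-density placement occupies the whole region regardless of C
  pf <- place_donor_cells(g, density = 1, clustering = 0.99, seed = 1)
  expect_identical(sort(pf$occupied), which(g$region))
  expect_error(place_donor_cells(g, density = 1.2, clustering = 0))
})

test_that("C = 0 placement matches uniform-random sampling", {
  g <- small_grid()
  stat_alg <- vapply(1:200, function(s)
    neighbor_fraction(g, place_donor_cells(g, 0.25, 0, seed = s)),
    numeric(1))
  # oracle: direct uniform sampling of the same number of region nodes
  region <- which(g$region)
  n_occ <- as.integer(ceiling(0.25 * length(region)))
  set.seed(1000)
  stat_unif <- vapply(1:200, function(s) {
    occ_nodes <- sample(region, n_occ)
    fake <- list(occupied = occ_nodes)
    class(fake) <- "donor_placement"
    neighbor_fraction(g, fake)
  }, numeric(1))
  se <- sqrt(var(stat_alg) / 200 + var(stat_unif) / 200)
  expect_lt(abs(mean(stat_alg) - mean(stat_unif)), 4 * se + 0.005)
})

test_that("clustering statistic increases with C at fixed density", {
  g <- small_grid()
  means <- vapply(c(0.6, 0.9, 0.99), function(C)
    mean(vapply(1:20, function(s)
      neighbor_fraction(g, place_donor_cells(g, 0.25, C, seed = s)),
      numeric(1))), numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("light field follows the closed-form exponential decay", {
  g <- small_grid()
  lf <- irradiance_field(10, g, illumination = "edge", delta = 1.84)
  expect_equal(lf$irradiance, 10 * exp(-g$y / 1.84), tolerance = 1e-12)
  i0 <- lf$irradiance[g$y == 0]
  expect_true(all(i0 == 10))                       # depth 0 -> E0
  node_d <- which.min(abs(g$y - 1.8))              # grid point nearest delta
  expect_equal(lf$irradiance[node_d], 10 * exp(-g$y[node_d] / 1.84))
  expect_true(all(lf$irradiance >= 0))
  uni <- irradiance_field(3, g, illumination = "uniform")
  expect_true(all(uni$irradiance == 3))
})

test_that("a donor-free strip conducts one planar wave per stimulus", {
  g <- tissue_grid(width = 8, height = 1, spacing = 0.2, d_diff = 0.1,
                   region_radius = 0)
  m <- tissue_model(g, NULL)
  sim <- simulate_monodomain(m, 60, pacing = stimulus_protocol(
    "electrical", 72, 2, onset = 5), record_dt = 60)
  amap <- activation_map(sim)
  expect_true(all(!is.na(sim$activation)))
  # activation monotone along the propagation direction
  row <- amap[3, ]
  expect_true(all(diff(row[g$x[1:g$nx] > 0.6]) > 0))
  # CV in the physiological range and convergent under refinement
  n1 <- which.min(abs(g$x - 2) + g$y); n2 <- which.min(abs(g$x - 6) + g$y)
  cv1 <- conduction_velocity(sim, n1, n2)
  expect_gt(cv1, 300); expect_lt(cv1, 900)  # mm/s
  gf <- tissue_grid(width = 8, height = 1, spacing = 0.1, d_diff = 0.1,
                    region_radius = 0)
  mf <- tissue_model(gf, NULL, dt = 0.01)
  simf <- simulate_monodomain(mf, 60, pacing = stimulus_protocol(
    "electrical", 72, 2, onset = 5), record_dt = 60)
  cv2 <- conduction_velocity(simf,
                             which.min(abs(gf$x - 2) + gf$y),
                             which.min(abs(gf$x - 6) + gf$y))
  expect_lt(abs(cv2 - cv1) / cv2, 0.1)
})

test_that("conduction velocity handles constructed and degenerate maps", {
  g <- tissue_grid(width = 4, height = 1, spacing = 0.2, d_diff = 0.1,
                   region_radius = 0)
  m <- tissue_model(g, NULL)
  sim <- simulate_monodomain(m, 5, record_dt = 5)  # nothing activates
  expect_true(all(is.na(sim$activation)))
  # constructed planar wave at exactly 500 mm/s
  sim$activation <- 10 + g$x / 0.5  # ms; 0.5 mm/ms
  n1 <- which(g$x == 1 & g$y == 0); n2 <- which(g$x == 3 & g$y == 0)
  expect_equal(conduction_velocity(sim, n1, n2), 500, tolerance = 1e-9)
  # simultaneous activation flagged as unresolved
  sim$activation[] <- 7
  expect_warning(cv <- conduction_velocity(sim, n1, n2), "simultaneous")
  expect_identical(cv, Inf)
})

test_that("with negligible conductivity each node behaves as an isolated cell", {
  g <- tissue_grid(width = 1, height = 0.4, spacing = 0.2, d_diff = 1e-9,
                   region_radius = 0)
  m <- tissue_model(g, NULL, dt = 0.02)
  pace <- stimulus_protocol("electrical", 72, 2, onset = 10)
  sim <- simulate_monodomain(m, 300, pacing = pace,
                             pace_nodes = seq_len(g$nx * g$ny),
                             record_dt = 0.5, probes = 5)
  single <- simulate_cell("myocyte", duration = 300, electrical = pace,
                          fix_nak = TRUE, record_dt = 0.5)
  expect_lt(max(abs(sim$v_probe[, 1] - single$v)), 0.5)
})

test_that("the diffusion stability bound is enforced", {
  g <- tissue_grid(width = 5, height = 5, spacing = 0.1, d_diff = 0.1)
  expect_error(tissue_model(g, NULL, dt = 0.05), "stability")
})

test_that("tissue runs are seed-deterministic end to end", {
  g <- small_grid()
  p <- place_donor_cells(g, 0.25, 0.9, n_fb = 20, seed = 3)
  m <- tissue_model(g, p, g_gj = 5)
  run <- function() {
    s <- simulate_monodomain(m, 40, light = list(e0 = 5, onset = 5,
                                                 duration = 20),
                             record_dt = 2, probes = p$occupied[1])
    s$v_probe
  }
  expect_identical(run(), run())
})
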