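## Reduced-scale monodomain tissue simulation: stochastic donor placement by
## density D and clustering C, depth-dependent illumination, electrical
## pacing preamble and the tissue-level optical threshold search.

#' Build a regular 2D tissue grid
#'
#' A rectangular sheet of host ventricular myocytes with a circular donor
#' target region. Node order is row-major with x fastest
#' (`node = (iy - 1) * nx + ix`).
#'
#' @param width,height sheet dimensions, mm
#' @param spacing node spacing, mm
#' @param d_diff effective monodomain diffusion coefficient, mm^2/ms
#'   (the default gives a planar conduction velocity in the 50-70 cm/s
#'   range in donor-free tissue)
#' @param region_center donor target region center `(x, y)`, mm
#' @param region_radius donor target region radius, mm
#' @return an object of class `tissue_grid`
#' @export
tissue_grid <- function(width = 10, height = 10, spacing = 0.1,
                        d_diff = 0.1,
                        region_center = c(width / 2, height / 2),
                        region_radius = 3) {
  stopifnot(spacing > 0, width >= spacing, height >= spacing, d_diff > 0)
  nx <- as.integer(round(width / spacing)) + 1L
  ny <- as.integer(round(height / spacing)) + 1L
  ix <- rep(seq_len(nx) - 1L, times = ny)
  iy <- rep(seq_len(ny) - 1L, each = nx)
  x <- ix * spacing
  y <- iy * spacing
  region <- (x - region_center[1])^2 + (y - region_center[2])^2 <=
    region_radius^2
  structure(list(
    nx = nx, ny = ny, spacing = spacing, d_diff = d_diff,
    x = x, y = y, region = region,
    region_center = region_center, region_radius = region_radius
  ), class = "tissue_grid")
}

grid_neighbors <- function(grid, node) {
  # 4-neighborhood, 1-based node indices
  nx <- grid$nx; ny <- grid$ny
  ix <- (node - 1L) %% nx
  iy <- (node - 1L) %/% nx
  out <- integer(0)
  if (ix > 0) out <- c(out, node - 1L)
  if (ix < nx - 1L) out <- c(out, node + 1L)
  if (iy > 0) out <- c(out, node - nx)
  if (iy < ny - 1L) out <- c(out, node + nx)
  out
}

#' Stochastically place donor-cell-bearing nodes
#'
#' Iterative growth: the first occupied node is drawn uniformly from the
#' target region; each subsequent node is, with probability `clustering`,
#' drawn uniformly from the unoccupied region neighbours of the occupied
#' set (falling back to a uniform draw when none exist), and otherwise
#' drawn uniformly from all unoccupied region nodes. The achieved count is
#' exactly `ceiling(density * |region|)`.
#'
#' @param grid [tissue_grid()]
#' @param density donor density D in `(0, 1]` (proportion of the target
#'   region)
#' @param clustering clustering parameter C in `[0, 1)`
#' @param n_fb donor cells per occupied node
#' @param seed integer RNG seed (placement is deterministic given the seed)
#' @return an object of class `donor_placement`: `occupied` (node
#'   indices), `density`, `clustering`, `n_fb`, `seed`, `n_target`
#' @export
place_donor_cells <- function(grid, density, clustering = 0, n_fb = 20,
                              seed = 1) {
  stopifnot(inherits(grid, "tissue_grid"),
            density > 0, density <= 1, clustering >= 0, clustering < 1,
            n_fb >= 1)
  region_nodes <- which(grid$region)
  if (length(region_nodes) < 1) stop("target region contains no nodes")
  n_occ <- as.integer(ceiling(density * length(region_nodes)))
  if (n_occ > length(region_nodes))
    stop("region too small for the requested density")

  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()),
            add = TRUE)
  }
  set.seed(seed)

  in_region <- logical(grid$nx * grid$ny)
  in_region[region_nodes] <- TRUE
  occ <- logical(grid$nx * grid$ny)
  frontier <- integer(0)  # unoccupied region neighbours of occupied set
  n_taken <- 0L

  take <- function(node) {
    occ[node] <<- TRUE
    n_taken <<- n_taken + 1L
    nb <- grid_neighbors(grid, node)
    fr <- unique(c(frontier, nb[in_region[nb]]))
    frontier <<- fr[!occ[fr]]
  }

  take(sample_one(region_nodes))
  while (n_taken < n_occ) {
    if (length(frontier) > 0 && stats::runif(1) < clustering) {
      take(sample_one(frontier))
    } else {
      take(sample_one(region_nodes[!occ[region_nodes]]))
    }
  }
  occupied <- which(occ)

  structure(list(
    occupied = occupied, density = density, clustering = clustering,
    n_fb = n_fb, seed = seed, n_target = n_occ,
    n_region = length(region_nodes)
  ), class = "donor_placement")
}

sample_one <- function(x) if (length(x) == 1L) x else x[sample.int(length(x), 1L)]

#' Mean occupied-neighbour fraction of a placement
#'
#' Clustering statistic: for each occupied node, the fraction of its
#' 4-neighbours (within the sheet) that are also occupied, averaged over
#' occupied nodes. Increases with the clustering parameter C at fixed
#' density.
#'
#' @param grid [tissue_grid()]
#' @param placement [place_donor_cells()]
#' @return scalar in `[0, 1]`
#' @export
neighbor_fraction <- function(grid, placement) {
  occ <- logical(grid$nx * grid$ny)
  occ[placement$occupied] <- TRUE
  mean(vapply(placement$occupied, function(node) {
    nb <- grid_neighbors(grid, node)
    mean(occ[nb])
  }, numeric(1)))
}

#' Per-node irradiance under exponential depth decay
#'
#' `E(depth) = E0 exp(-depth / delta)`, with penetration depth
#' `delta = 1.84` mm for 488 nm blue light.
#'
#' @param e0 surface irradiance, mW/mm^2
#' @param grid [tissue_grid()]
#' @param illumination `"uniform"` (no depth; the whole sheet at the
#'   surface) or `"edge"` (light enters at the y = 0 edge and the y
#'   coordinate is depth)
#' @param depth optional explicit per-node depth vector, mm (overrides
#'   `illumination`)
#' @param delta penetration depth, mm
#' @return an object of class `light_field`: data.frame `(node, depth,
#'   irradiance)` with attributes `e0` and `delta`
#' @export
irradiance_field <- function(e0, grid, illumination = c("uniform", "edge"),
                             depth = NULL, delta = 1.84) {
  illumination <- match.arg(illumination)
  stopifnot(e0 >= 0, delta > 0)
  n <- grid$nx * grid$ny
  if (is.null(depth)) {
    depth <- switch(illumination, uniform = rep(0, n), edge = grid$y)
  }
  stopifnot(length(depth) == n, all(depth >= 0))
  out <- data.frame(node = seq_len(n), depth = depth,
                    irradiance = e0 * exp(-depth / delta))
  attr(out, "e0") <- e0
  attr(out, "delta") <- delta
  class(out) <- c("light_field", "data.frame")
  out
}

#' Assemble a tissue model
#'
#' Combines grid, donor placement and electrophysiological parameters into
#' a runnable monodomain model. Occupied nodes carry a fibroblast+ChR2
#' donor bundle (one representative donor ODE scaled by `n_fb`, exact for
#' identical mutually uncoupled donors) coupled to the node's host myocyte.
#'
#' @param grid [tissue_grid()]
#' @param placement [place_donor_cells()] or `NULL` for donor-free tissue
#' @param g_gj per-junction gap-junctional conductance, nS
#' @param host_ina_fraction host fast-Na+ scale in `[0, 1]`
#' @param host_cm host capacitance for junctional-current conversion, pF
#' @param host_fix_nak hold host intracellular Na+/K+ fixed (drift guard)
#' @param fib_params,chr2_params donor model parameters
#' @param illumination,delta light geometry, see [irradiance_field()]
#' @param dt integration step, ms (must satisfy the diffusion stability
#'   bound `dt <= spacing^2 / (4 d_diff)`)
#' @return an object of class `tissue_model`
#' @export
tissue_model <- function(grid, placement = NULL, g_gj = 2,
                         host_ina_fraction = 1, host_cm = 165,
                         host_fix_nak = TRUE,
                         fib_params = fibroblast_params(),
                         chr2_params = optogap::chr2_params(),
                         illumination = "uniform", delta = 1.84,
                         dt = 0.02) {
  stopifnot(inherits(grid, "tissue_grid"))
  cfl <- grid$spacing^2 / (4 * grid$d_diff)
  if (dt > cfl)
    stop(sprintf("dt = %g ms violates the diffusion stability bound %g ms",
                 dt, cfl))
  structure(list(
    grid = grid, placement = placement, g_gj = g_gj,
    host_ina_fraction = host_ina_fraction, host_cm = host_cm,
    host_fix_nak = host_fix_nak, fib_params = fib_params,
    chr2_params = chr2_params, illumination = illumination, delta = delta,
    dt = dt
  ), class = "tissue_model")
}

tissue_default_states <- function(model) {
  nnode <- model$grid$nx * model$grid$ny
  host <- matrix(rep(unname(myocyte_state()), each = nnode), nrow = nnode)
  nocc <- if (is.null(model$placement)) 0L else
    length(model$placement$occupied)
  donor <- matrix(rep(c(unname(fibroblast_state()), unname(chr2_state())),
                      each = nocc), nrow = nocc)
  list(host = host, donor = donor)
}

pace_edge_nodes <- function(grid, edge_mm = 0.5) {
  which(grid$x <= edge_mm)
}

#' Run a monodomain tissue simulation
#'
#' Operator-splitting integration (reaction per node, explicit diffusion of
#' the host membrane potential, no-flux boundaries). Electrical pacing is
#' applied to a strip of nodes; a single optical pulse drives the ChR2 of
#' the placed donors, scaled per node by the light field.
#'
#' @param model [tissue_model()]
#' @param duration simulated time, ms
#' @param light `NULL` or a list with `e0` (surface irradiance, mW/mm^2),
#'   `onset` and `duration` (ms)
#' @param pacing `NULL` or an electrical [stimulus_protocol()]
#' @param pace_nodes nodes receiving the pacing stimulus (default: the
#'   `x <= 0.5` mm edge strip)
#' @param init states from a previous run (list `host`, `donor`);
#'   default: published single-cell initial conditions everywhere
#' @param record_dt probe sampling interval, ms
#' @param act_from record each node's first upward 0 mV crossing at
#'   `t >= act_from` (ms)
#' @param probes node indices whose host Vm is recorded
#' @return an object of class `tissue_sim`: `time`, `v_probe`,
#'   `activation` (per-node activation time, NA if never activated),
#'   `final` states, `unstable` flag
#' @export
simulate_monodomain <- function(model, duration, light = NULL,
                                pacing = NULL,
                                pace_nodes = pace_edge_nodes(model$grid),
                                init = NULL, record_dt = 1, act_from = 0,
                                probes = integer(0)) {
  stopifnot(inherits(model, "tissue_model"))
  if (is.null(init)) init <- tissue_default_states(model)
  occ <- if (is.null(model$placement)) integer(0) else
    model$placement$occupied
  n_fb <- if (is.null(model$placement)) 0 else model$placement$n_fb

  e0 <- 0; opt_onset <- 0; opt_dur <- 0
  rel_irr <- rep(1, length(occ))
  if (!is.null(light)) {
    e0 <- light$e0; opt_onset <- light$onset; opt_dur <- light$duration
    lf <- irradiance_field(1, model$grid, illumination = model$illumination,
                           delta = model$delta)
    rel_irr <- lf$irradiance[occ]
  }

  pace_vec <- as_stim_vec(pacing)
  if (is.null(pacing)) pace_nodes <- integer(0)

  res <- tissue_run_cpp(
    model$grid$nx, model$grid$ny, model$grid$spacing, model$grid$d_diff,
    init$host, init$donor, as.integer(occ - 1L), n_fb,
    as_fib_vec(model$fib_params), as_chr2_vec(model$chr2_params),
    model$g_gj, model$host_ina_fraction, model$host_cm,
    model$host_fix_nak, rel_irr, e0, opt_onset, opt_dur,
    as.integer(pace_nodes - 1L), pace_vec, duration, model$dt, record_dt,
    act_from, as.integer(probes - 1L))

  if (isTRUE(res$unstable))
    warning(sprintf("numerical instability detected at t = %.3f ms",
                    res$t_unstable), call. = FALSE)

  structure(list(
    time = res$time, v_probe = res$v_probe, activation = res$activation,
    final = list(host = res$host_final, donor = res$donor_final),
    unstable = res$unstable, t_unstable = res$t_unstable, model = model
  ), class = "tissue_sim")
}

#' Activation map of a tissue simulation
#'
#' @param sim [simulate_monodomain()] result
#' @return an `ny x nx` matrix of activation times (ms; NA = not activated)
#' @export
activation_map <- function(sim) {
  g <- sim$model$grid
  matrix(sim$activation, nrow = g$ny, ncol = g$nx, byrow = TRUE)
}

#' Conduction velocity along a straight path between two nodes
#'
#' `CV = distance / (t2 - t1)` from the activation map; simultaneous
#' activation (time difference below `min_dt`) is flagged as infinite.
#'
#' @param sim [simulate_monodomain()] result
#' @param from,to node indices
#' @param min_dt smallest meaningful activation-time difference, ms
#' @return conduction velocity, mm/s (`Inf` with a warning if the path
#'   activates simultaneously; `NA` if either node never activates)
#' @export
conduction_velocity <- function(sim, from, to, min_dt = 1e-6) {
  g <- sim$model$grid
  t1 <- sim$activation[from]
  t2 <- sim$activation[to]
  if (is.na(t1) || is.na(t2)) return(NA_real_)
  dist <- sqrt((g$x[to] - g$x[from])^2 + (g$y[to] - g$y[from])^2)
  dtt <- abs(t2 - t1)
  if (dtt < min_dt) {
    warning("simultaneous activation along the path; CV is unresolved",
            call. = FALSE)
    return(Inf)
  }
  dist / dtt * 1000  # mm/s
}

#' Tissue-level optical excitation threshold
#'
#' Applies the electrical pacing preamble to attain a paced quasi-steady
#' state, then bisects the surface irradiance of a single optical pulse to
#' the weakest stimulus that captures the sheet. Capture is defined as
#' activation of at least `capture_frac` of the nodes after the pulse.
#'
#' @param model [tissue_model()] (must contain a donor placement)
#' @param pulse_duration optical pulse duration, ms
#' @param preamble electrical pacing preamble (default per the assay
#'   protocol: 72 pA/pF, 2 ms pulses at 1 Hz, 10 stimuli)
#' @param preamble_tail time after the last preamble stimulus before the
#'   optical test, ms
#' @param bracket,rel_tol,cap bisection controls as in
#'   [find_excitation_threshold()]
#' @param capture_frac fraction of nodes that must activate for capture
#' @param window capture evaluation window after pulse onset, ms
#' @return an object of class `threshold_result` with the additional field
#'   `capture_fraction` at the final bracket endpoints
#' @export
tissue_excitation_threshold <- function(model, pulse_duration = 10,
                                        preamble = stimulus_protocol(
                                          "electrical", 72, 2,
                                          period = 1000, n_pulses = 10,
                                          onset = 10),
                                        preamble_tail = 400,
                                        bracket = c(0, 1), rel_tol = 0.01,
                                        cap = 100, capture_frac = 0.9,
                                        window = 300) {
  stopifnot(inherits(model, "tissue_model"), !is.null(model$placement))

  pre_dur <- preamble$onset + (preamble$n_pulses - 1) *
    max(preamble$period, preamble$pulse_duration) + preamble_tail
  pre <- simulate_monodomain(model, pre_dur, pacing = preamble,
                             record_dt = pre_dur)
  st <- pre$final

  onset <- 10
  n_nodes <- model$grid$nx * model$grid$ny
  run <- function(e0) {
    sim <- simulate_monodomain(
      model, onset + window,
      light = list(e0 = e0, onset = onset, duration = pulse_duration),
      init = st, record_dt = onset + window, act_from = onset)
    mean(!is.na(sim$activation))
  }
  captures <- function(frac) frac >= capture_frac

  f_lo <- run(bracket[1])
  if (captures(f_lo))
    stop("tissue captures with no light; cannot bisect a threshold")
  lo <- bracket[1]; hi <- bracket[2]; iter <- 0L
  f_hi <- run(hi)
  while (!captures(f_hi) && hi < cap) {
    lo <- hi; hi <- min(10 * hi, cap); f_hi <- run(hi); iter <- iter + 1L
  }
  if (!captures(f_hi)) {
    return(structure(list(
      e_th = NA_real_, no_capture = TRUE, bracket = c(lo, hi),
      iterations = iter, capture_fraction = c(low = f_lo, high = f_hi),
      pulse_duration = pulse_duration, config = model
    ), class = "threshold_result"))
  }
  while ((hi - lo) > rel_tol * hi) {
    mid <- (lo + hi) / 2
    fm <- run(mid)
    if (captures(fm)) { hi <- mid; f_hi <- fm } else { lo <- mid; f_lo <- fm }
    iter <- iter + 1L
  }
  structure(list(
    e_th = hi, no_capture = FALSE, bracket = c(lo, hi), iterations = iter,
    capture_fraction = c(low = f_lo, high = f_hi),
    pulse_duration = pulse_duration, config = model
  ), class = "threshold_result")
}
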