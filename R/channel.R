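#' Slit-channel configuration
#'
#' Full configuration of a 2D slit-channel blood-flow simulation: geometry,
#' hematocrit, suspended chains, flow driving, sampling schedule and all
#' model parameters. Defaults follow the standard setup: width `W = 20` um,
#' length `L = 28.6 D_r`, 6 chains, bounce-back walls with an adaptive
#' near-wall shear force.
#'
#' @param W channel width (micrometres).
#' @param L channel length along the periodic flow axis; defaults to
#'   `28.6 * D_r` of the RBC model.
#' @param H_t target hematocrit (RBC area fraction), `0 <= H_t < 0.8`.
#' @param N_VWF number of suspended chains.
#' @param chain_N beads per chain.
#' @param chain_mode `"attractive"`, `"repulsive"`, or `"mixed"` (half
#'   attractive, half repulsive — a paired comparison in one suspension).
#' @param g body acceleration along x driving the flow.
#' @param density fluid number density (particles/um^2).
#' @param kBT thermal energy of the solvent.
#' @param dt integration time step.
#' @param weight_exponent DPD random-force weight exponent.
#' @param warmup_steps,sample_steps,stride sampling schedule: steps
#'   discarded, steps sampled, snapshot stride.
#' @param seed RNG seed for the whole run.
#' @param rbc an [rbc_params()].
#' @param chain a [chain_params()] (its `N`/`mode` are overridden by
#'   `chain_N` / `chain_mode`).
#' @param adaptive_gain,adaptive_interval near-wall shear-force controller
#'   gain and update interval (steps).
#' @param init_flow `"none"` or `"parabola"` (pre-set the fluid velocities
#'   to the expected parabolic profile to shorten the transient).
#' @param eta_guess viscosity estimate used by the parabolic
#'   initialization.
#' @param relax_steps damped structure-relaxation steps before the fluid is
#'   added.
#' @param chain_init `"uniform"` (random positions across the width) or
#'   `"stratified"` (compact coils at the RBC-core edge near each wall and
#'   at the centreline, in equal numbers, with both polymer modes
#'   represented at every height). The stratified start approaches the
#'   stationary cross-stream distribution from both sides, which shortens
#'   the transient needed to resolve near-wall retention differences in
#'   scaled-down runs.
#' @param temp_action `"none"`, `"warn"` or `"abort"` on a kinetic
#'   temperature excursion beyond `temp_tol` during sampling.
#' @param temp_tol relative temperature excursion tolerance.
#' @param record_vel record velocities in snapshots.
#' @export
channel_config <- function(W = 20, L = NULL, H_t = 0, N_VWF = 6L,
                           chain_N = 26L,
                           chain_mode = c("attractive", "repulsive", "mixed"),
                           g = 0.02, density = 6, kBT = 1, dt = 0.005,
                           weight_exponent = 1,
                           warmup_steps = 10000L, sample_steps = 20000L,
                           stride = 200L, seed = 1L,
                           rbc = rbc_params(), chain = chain_params(),
                           adaptive_gain = 0.05, adaptive_interval = 100L,
                           init_flow = c("none", "parabola"), eta_guess = 2.5,
                           relax_steps = 4000L,
                           chain_init = c("uniform", "stratified"),
                           temp_action = c("warn", "none", "abort"),
                           temp_tol = 0.1, record_vel = TRUE) {
  chain_mode <- match.arg(chain_mode)
  init_flow <- match.arg(init_flow)
  chain_init <- match.arg(chain_init)
  temp_action <- match.arg(temp_action)
  if (is.null(L)) L <- 28.6 * rbc$D_r
  if (H_t < 0 || H_t >= 0.8) stop("H_t must satisfy 0 <= H_t < 0.8")
  if (W <= 0 || L <= 0) stop("box dimensions must be > 0")
  if (N_VWF < 0) stop("N_VWF must be >= 0")
  chain$N <- as.integer(chain_N)
  chain$L_VWF <- (chain$N - 1) * chain$l_b
  structure(list(W = W, L = L, H_t = H_t, N_VWF = as.integer(N_VWF),
                 chain_mode = chain_mode, g = g, density = density,
                 kBT = kBT, dt = dt, weight_exponent = weight_exponent,
                 warmup_steps = as.integer(warmup_steps),
                 sample_steps = as.integer(sample_steps),
                 stride = as.integer(stride), seed = as.integer(seed),
                 rbc = rbc, chain = chain,
                 adaptive_gain = adaptive_gain,
                 adaptive_interval = as.integer(adaptive_interval),
                 init_flow = init_flow, eta_guess = eta_guess,
                 relax_steps = as.integer(relax_steps),
                 chain_init = chain_init,
                 temp_action = temp_action, temp_tol = temp_tol,
                 record_vel = record_vel),
            class = "channel_config")
}

config_dpd_params <- function(config) {
  dpd_params(kBT = config$kBT, dt = config$dt,
             weight_exponent = config$weight_exponent, seed = config$seed)
}

#' Build frozen-particle walls
#'
#' Slabs of frozen particles with the same density and (disordered)
#' structure as the bulk fluid, of thickness `r_c` beyond each wall plane
#' at y = 0 and y = W. Their interactions with the fluid are identical in
#' form to fluid-fluid interactions; they never move.
#'
#' @param config a [channel_config()].
#' @param r_c interaction cutoff (slab thickness).
#' @param seed RNG seed.
#' @return a [particle_set()] with species `"wall"`.
#' @export
build_walls <- function(config, r_c = 1, seed = config$seed) {
  n_side <- round(config$density * config$L * r_c)
  with_seed(seed + 7L, {
    lo <- cbind(runif(n_side, 0, config$L), runif(n_side, -r_c, 0))
    hi <- cbind(runif(n_side, 0, config$L),
                runif(n_side, config$W, config$W + r_c))
    particle_set(rbind(lo, hi), species = "wall")
  })
}

#' Bounce-back wall reflection
#'
#' Any mobile particle that crossed a wall plane after a drift is mirrored
#' back inside the channel and its full velocity vector is negated; this
#' approximates no-slip walls better than specular reflection.
#'
#' @param pos N x 2 positions after the drift.
#' @param vel N x 2 velocities.
#' @param wall_planes y positions of the two walls, `c(0, W)`.
#' @param mobile logical mask; frozen particles are left untouched.
#' @param max_depth error if a particle is beyond a wall by more than this
#'   (one slab thickness): that signals a numerical blow-up.
#' @return list with corrected `pos`, `vel` and logical `reflected`.
#' @export
bounce_back <- function(pos, vel, wall_planes, mobile = NULL, max_depth = 1) {
  lo <- wall_planes[1]; hi <- wall_planes[2]
  if (is.null(mobile)) mobile <- rep(TRUE, nrow(pos))
  if (any(pos[mobile, 2] < lo - max_depth | pos[mobile, 2] > hi + max_depth))
    stop("particle beyond wall by more than one slab thickness (blow-up)")
  below <- mobile & pos[, 2] < lo
  above <- mobile & pos[, 2] > hi
  pos[below, 2] <- 2 * lo - pos[below, 2]
  pos[above, 2] <- 2 * hi - pos[above, 2]
  refl <- below | above
  vel[refl, ] <- -vel[refl, ]
  list(pos = pos, vel = vel, reflected = refl)
}

#' Place RBCs and chains at a target hematocrit
#'
#' The number of RBCs is `round(H_t * W * L / A_0_2d)`. Cells are placed as
#' ellipses (matching circumference and target area) on a staggered,
#' jittered lattice aligned with the flow, then relaxed with damped
#' membrane dynamics and pure excluded-volume interactions; chains are
#' placed as compact coils at uniformly random positions. Reproducible for
#' a fixed seed.
#'
#' @param config a [channel_config()].
#' @param seed RNG seed (defaults to the config seed).
#' @return list with `particles` (structures only), `rings`, `chains`
#'   registries, `n_rbc`, and `H_t_realized`.
#' @export
place_cells_and_chains <- function(config, seed = config$seed) {
  rp <- config$rbc
  n_rbc <- round(config$H_t * config$W * config$L / rp$A_0_2d)
  kBT <- config$kBT
  sets <- list(); rings <- list(); chains <- list()
  start <- 1L
  if (n_rbc > 0) {
    ab <- ellipse_axes(rp$L_0, rp$A_0_2d)
    slots <- rbc_lattice_slots(n_rbc, config$W, config$L, ab)
    jit <- with_seed(seed + 11L, cbind(runif(n_rbc, -0.25, 0.25),
                                       runif(n_rbc, -0.1, 0.1),
                                       runif(n_rbc, -0.1, 0.1)))
    for (k in seq_len(n_rbc)) {
      ctr <- c((slots[k, 1] + jit[k, 1]) %% config$L,
               min(max(slots[k, 2] + jit[k, 2], ab["b"] + 0.45),
                   config$W - ab["b"] - 0.45))
      built <- build_rbc(ctr, rp, shape = "ellipse",
                         orientation = jit[k, 3], start = start, kBT = kBT)
      sets[[length(sets) + 1L]] <- built$particles
      rings[[length(rings) + 1L]] <- built$ring
      start <- start + rp$N_v
    }
  }
  if (config$N_VWF > 0) {
    cp <- config$chain
    modes <- switch(config$chain_mode,
      attractive = rep("attractive", config$N_VWF),
      repulsive = rep("repulsive", config$N_VWF),
      mixed = rep(c("attractive", "repulsive"), length.out = config$N_VWF))
    r_coil <- cp$l_b * 0.62 * sqrt(cp$N) + 0.4
    strat <- identical(config$chain_init, "stratified")
    if (strat) {
      # compact coils at the core edge near each wall and at the
      # centreline, modes interleaved so both see the same initial
      # heights. The edge start probes the discriminating mechanism
      # directly (collisions with the RBC core displace the softer
      # repulsive chain centreward while the compact globule persists
      # near the wall); the centreline chains sample the low-shear core.
      y0 <- c(max(r_coil, 1.2), config$W - max(r_coil, 1.2), config$W / 2)
      ys <- rep(y0, length.out = config$N_VWF)[order(rep(seq_along(y0),
        length.out = config$N_VWF))]
    }
    pts <- with_seed(seed + 13L, {
      p <- cbind(runif(config$N_VWF, 0, config$L),
                 runif(config$N_VWF, r_coil, config$W - r_coil),
                 runif(config$N_VWF, 0, 2 * pi))
      if (strat) p[, 2] <- ys
      p
    })
    for (k in seq_len(config$N_VWF)) {
      cpk <- cp; cpk$mode <- modes[k]
      built <- build_chain(pts[k, 1:2], cpk, conformation = "coil",
                           orientation = pts[k, 3], start = start, kBT = kBT)
      sets[[length(sets) + 1L]] <- built$particles
      chains[[length(chains) + 1L]] <- built$chain
      start <- start + cp$N
    }
  }
  if (length(sets) == 0L)
    return(list(particles = NULL, rings = list(), chains = list(),
                n_rbc = 0L, H_t_realized = 0))
  particles <- if (length(sets) == 1L) sets[[1L]] else do.call(bind_particles, sets)
  # fix struct ids to registry order (bind_particles shifts them uniquely)
  box <- box_spec(config$L, config$W)
  if (config$relax_steps > 0 && (n_rbc > 0 || length(chains) > 1L)) {
    particles <- relax_structures(particles, rings, chains, box, config)
  }
  Ht_real <- if (n_rbc > 0)
    sum(vapply(rings, function(r) rbc_area(r, particles, box), numeric(1))) /
      (config$W * config$L) else 0
  list(particles = particles, rings = rings, chains = chains,
       n_rbc = as.integer(n_rbc), H_t_realized = Ht_real)
}

# staggered lattice of ellipse centres; error if the target count cannot fit
rbc_lattice_slots <- function(n_rbc, W, L, ab) {
  a <- ab[["a"]]; b <- ab[["b"]]
  n_cols <- max(1L, floor(L / (2 * a + 0.25)))
  n_rows <- ceiling(n_rbc / n_cols)
  ymin <- b + 0.5; ymax <- W - b - 0.5
  if (n_rows > 1 && (ymax - ymin) / (n_rows - 1) < 2 * b + 0.15)
    stop("overcrowding: cannot place ", n_rbc,
         " RBCs; lower H_t or enlarge the channel")
  ys <- if (n_rows == 1) (ymin + ymax) / 2 else seq(ymin, ymax, length.out = n_rows)
  slots <- do.call(rbind, lapply(seq_len(n_rows), function(r) {
    x0 <- (L / n_cols) * (0.5 + 0.5 * (r %% 2))
    cbind((x0 + (seq_len(n_cols) - 1L) * L / n_cols) %% L, ys[r])
  }))
  slots[seq_len(n_rbc), , drop = FALSE]
}

relax_structures <- function(particles, rings, chains, box, config) {
  params <- config_dpd_params(config)
  sys <- build_system(particles, box, params, rings = rings, chains = chains)
  ctrl <- list(dt = 0.001, seed = as.double(config$seed),
               n_steps = as.double(config$relax_steps), warmup = 0,
               stride = 1, g = 0, bounce = TRUE, adaptive = FALSE,
               k_gain = 0, interval = 1, record = FALSE, record_vel = FALSE,
               damp = 5, fcap = 100, temp_tol = 1e9, temp_action = 0L,
               check_every = 1e9)
  res <- cpp_run_channel(particles$pos, particles$vel, sys, ctrl)
  particles$pos <- res$final_pos
  particles$vel <- particles$vel * 0
  particles
}

#' Run a slit-channel simulation
#'
#' Assembles fluid, frozen walls and suspended structures, applies the body
#' force along x, integrates with velocity-Verlet, and records snapshots
#' after the warmup. Periodic along x, bounce-back walls in y, with the
#' adaptive near-wall shear force keeping the no-slip condition. The run
#' log records the kinetic temperature, realized hematocrit and the mean
#' axial velocity trace.
#'
#' @param config a [channel_config()].
#' @param state optional list with `particles`, `rings`, `chains` (e.g. a
#'   previous run's final state) to continue from.
#' @return a [trajectory()] with metadata (`meta$manifest`) including the
#'   realized hematocrit, measured temperature and mean-velocity traces and
#'   the full parameter set.
#' @export
run_channel <- function(config, state = NULL) {
  box <- box_spec(config$L, config$W)
  params <- config_dpd_params(config)
  if (is.null(state)) {
    placed <- place_cells_and_chains(config)
    n_fluid <- round(config$density * config$L * config$W)
    fluid <- with_seed(config$seed + 3L,
      particle_set(cbind(runif(n_fluid, 0, config$L),
                         runif(n_fluid, 0, config$W)), species = "fluid"))
    walls <- build_walls(config, r_c = params$r_c)
    particles <- if (is.null(placed$particles)) bind_particles(fluid, walls)
                 else bind_particles(fluid, walls, placed$particles)
    particles <- thermal_velocities(particles, config$kBT,
                                    seed = config$seed + 5L)
    if (config$init_flow == "parabola") {
      v_max <- config$density * config$g * config$W^2 / (8 * config$eta_guess)
      y <- particles$pos[, 2]
      flu <- particles$species == .SPECIES[["fluid"]]
      particles$vel[flu, 1] <- particles$vel[flu, 1] +
        4 * v_max * (y[flu] / config$W) * (1 - y[flu] / config$W)
    }
    offset <- n_fluid + 2 * round(config$density * config$L * params$r_c)
    rings <- lapply(placed$rings, function(r) { r$start <- r$start + offset; r })
    chains <- lapply(placed$chains, function(ch) { ch$start <- ch$start + offset; ch })
    Ht_real <- placed$H_t_realized
  } else {
    particles <- state$particles
    rings <- state$rings
    chains <- state$chains
    Ht_real <- state$H_t_realized %||%
      (if (length(rings)) sum(vapply(rings, rbc_area, numeric(1),
                                     particles = particles, box = box)) /
         (config$W * config$L) else 0)
  }
  sys <- build_system(particles, box, params, rings = rings, chains = chains)
  n_steps <- config$warmup_steps + config$sample_steps
  ctrl <- list(dt = config$dt, seed = as.double(config$seed),
               n_steps = as.double(n_steps),
               warmup = as.double(config$warmup_steps),
               stride = as.double(config$stride), g = config$g,
               bounce = TRUE, adaptive = config$adaptive_gain > 0,
               k_gain = config$adaptive_gain,
               interval = as.double(config$adaptive_interval),
               record = TRUE, record_vel = config$record_vel, damp = 0,
               fcap = 0,
               temp_tol = config$temp_tol,
               temp_action = match(config$temp_action,
                                   c("none", "warn", "abort")) - 1L,
               check_every = 100)
  res <- cpp_run_channel(particles$pos, particles$vel, sys, ctrl)
  if (isTRUE(res$temp_flag) && config$temp_action == "warn")
    warning("kinetic temperature excursion beyond ", config$temp_tol * 100,
            "% of target during sampling")
  manifest <- run_manifest(config, Ht_real, res)
  trajectory(res$pos, vel = if (config$record_vel) res$vel else NULL,
             times = res$times, species = particles$species,
             struct_id = particles$struct_id,
             bead_index = particles$bead_index, box = box,
             rings = rings, chains = chains,
             meta = list(manifest = manifest,
                         final_state = list(
                           particles = particle_set(
                             res$final_pos, vel = res$final_vel,
                             species = species_label(particles$species),
                             struct_id = particles$struct_id,
                             bead_index = particles$bead_index),
                           rings = rings, chains = chains,
                           H_t_realized = Ht_real)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
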