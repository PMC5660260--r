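#' Neighbour pair list
#'
#' Cell-list search for all unordered particle pairs with minimum-image
#' distance below the cutoff, including pairs across the periodic x
#' boundary.
#'
#' @param particles a [particle_set()].
#' @param r_c cutoff distance (micrometres); must not exceed any cell-grid
#'   dimension.
#' @param box a [box_spec()].
#' @param wall_pad extent of the domain beyond the wall planes occupied by
#'   frozen wall particles (ignored for a periodic box).
#' @return integer matrix with columns `i`, `j` (`i < j`, 1-based).
#' @export
build_neighbor_list <- function(particles, r_c, box, wall_pad = r_c) {
  if (r_c <= 0) stop("r_c must be > 0")
  out <- cpp_neighbor_pairs(particles$pos, box$length_x, box$width_W, r_c,
                            box$periodic_x, box$periodic_y,
                            if (box$periodic_y) 0 else wall_pad)
  colnames(out) <- c("i", "j")
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' DPD pair forces
#'
#' Per-particle sum of the conservative, dissipative and random DPD pair
#' forces, plus (optionally) every other interaction in the system. The
#' random term uses one symmetric unit-variance draw per pair per step,
#' scaled by `dt^(-1/2)`; the draw is keyed by `(seed, step, pair)` so the
#' result is independent of pair enumeration order. Equal and opposite
#' forces act on the two partners of every pair (momentum conservation).
#'
#' @param particles a [particle_set()].
#' @param params a [dpd_params()]; the fluctuation-dissipation relation is
#'   built in.
#' @param box a [box_spec()].
#' @param step integer step index feeding the random-force stream.
#' @param components character vector of force components to include:
#'   any of `"conservative"`, `"dissipative"`, `"random"`, `"bond"`,
#'   `"lj"`, `"cross"`, `"spring"`, `"bend"`, `"area"`, or `"all"`.
#' @param rings,chains structure registries as built by [build_rbc()] /
#'   [build_chain()] (usually via [place_cells_and_chains()]).
#' @return N x 2 matrix of forces (energy/length).
#' @export
dpd_pair_forces <- function(particles, params, box, step = 0L,
                            components = c("conservative", "dissipative", "random"),
                            rings = list(), chains = list()) {
  sys <- build_system(particles, box, params, rings = rings, chains = chains)
  cpp_forces(particles$pos, particles$vel, sys, params$dt,
             as.double(params$seed), as.double(step), components)
}

#' Potential energy of the conservative interactions
#'
#' Named energies of every conservative term (DPD conservative, excluded
#' volume, chain bonds and LJ, ring springs, bending, area constraint).
#' The dissipative and random forces have no potential.
#'
#' @inheritParams dpd_pair_forces
#' @return named numeric vector with attribute `total`.
#' @export
system_energy <- function(particles, params, box,
                          components = "all", rings = list(), chains = list()) {
  sys <- build_system(particles, box, params, rings = rings, chains = chains)
  cpp_energy(particles$pos, sys, components)
}

#' One velocity-Verlet step
#'
#' Standard kick-drift-kick update. Frozen (wall) particles never move.
#' Reflections (periodic wrap in x, bounce-back at walls) are applied after
#' the drift. This R-level stepper takes an arbitrary force evaluator and is
#' intended for small systems and tests; production runs use
#' [run_channel()], which drives the same update in compiled code.
#'
#' @param particles a [particle_set()].
#' @param force_evaluator function `(particles, step)` returning an N x 2
#'   force matrix for the current positions.
#' @param dt time step (`dt = 0` returns the state unchanged).
#' @param box optional [box_spec()]; if supplied, x is wrapped and, for a
#'   wall-bounded box, bounce-back reflection is applied at y = 0 and y = W.
#' @param step step index passed through to the force evaluator.
#' @return updated [particle_set()].
#' @export
velocity_verlet_step <- function(particles, force_evaluator, dt,
                                 box = NULL, step = 0L) {
  if (dt == 0) return(particles)
  mobile <- particles$species != .SPECIES[["wall"]]
  m <- particles$mass
  f <- force_evaluator(particles, step)
  if (!all(is.finite(f[mobile, ])))
    stop("non-finite force in velocity_verlet_step at step ", step)
  particles$vel[mobile, ] <- particles$vel[mobile, ] + 0.5 * dt * f[mobile, ] / m
  particles$pos[mobile, ] <- particles$pos[mobile, ] + dt * particles$vel[mobile, ]
  if (!is.null(box)) {
    particles$pos[, 1] <- particles$pos[, 1] %% box$length_x
    if (box$periodic_y) {
      particles$pos[, 2] <- particles$pos[, 2] %% box$width_W
    } else {
      bb <- bounce_back(particles$pos, particles$vel,
                        wall_planes = c(0, box$width_W), mobile = mobile)
      particles$pos <- bb$pos
      particles$vel <- bb$vel
    }
  }
  f <- force_evaluator(particles, step + 1L)
  if (!all(is.finite(f[mobile, ])))
    stop("non-finite force in velocity_verlet_step at step ", step + 1L)
  particles$vel[mobile, ] <- particles$vel[mobile, ] + 0.5 * dt * f[mobile, ] / m
  particles
}

#' Kinetic temperature estimate
#'
#' kBT estimated from the velocity variance about the mean flow,
#' `sum(m |v - vbar|^2) / (2 N - dof)` in 2D. With `drift_removal = TRUE`
#' the mean is taken per wall-normal bin, which makes the estimate
#' insensitive to an imposed flow profile (and exactly Galilean invariant).
#'
#' @param particles a [particle_set()]; needs at least 2 mobile particles.
#' @param drift_removal subtract per-bin mean velocities before taking the
#'   variance.
#' @param n_bins number of wall-normal bins used for drift removal.
#' @param W channel width used for binning (defaults to the data range).
#' @return scalar kBT estimate (energy units).
#' @export
kinetic_temperature <- function(particles, drift_removal = TRUE,
                                n_bins = 10L, W = NULL) {
  mobile <- particles$species != .SPECIES[["wall"]]
  if (sum(mobile) < 2L)
    stop("kinetic temperature undefined: fewer than 2 mobile particles")
  v <- particles$vel[mobile, , drop = FALSE]
  m <- particles$mass
  if (drift_removal) {
    y <- particles$pos[mobile, 2]
    if (is.null(W)) W <- range(y)
    else W <- c(0, W)
    bins <- cut(y, breaks = seq(W[1], W[2], length.out = n_bins + 1L),
                include.lowest = TRUE)
    vbx <- ave(v[, 1], bins)
    vby <- ave(v[, 2], bins)
    dv <- cbind(v[, 1] - vbx, v[, 2] - vby)
    dof <- 2 * sum(mobile) - 2 * nlevels(droplevels(bins))
  } else {
    dv <- sweep(v, 2, colMeans(v))
    dof <- 2 * sum(mobile) - 2
  }
  sum(m * dv^2) / dof
}

#' Maxwell-Boltzmann velocity draw
#'
#' Thermal velocities at temperature kBT with the centre-of-mass drift
#' removed, for mobile particles only.
#'
#' @param particles a [particle_set()].
#' @param kBT thermal energy.
#' @param seed RNG seed.
#' @export
thermal_velocities <- function(particles, kBT, seed = 1L) {
  n <- n_particles(particles)
  mobile <- particles$species != .SPECIES[["wall"]]
  v <- with_seed(seed, matrix(rnorm(2 * n, sd = sqrt(kBT / particles$mass)), n, 2))
  v[!mobile, ] <- 0
  v[mobile, ] <- sweep(v[mobile, , drop = FALSE], 2,
                       colMeans(v[mobile, , drop = FALSE]))
  particles$vel <- v
  particles
}
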