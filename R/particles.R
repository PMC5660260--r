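#' Particle set
#'
#' Container for all point particles in a simulation: fluid, frozen wall
#' particles, RBC membrane vertices and polymer beads. Coordinates are in
#' micrometres (one simulation length unit corresponds to 1 micrometre);
#' velocities are in length per simulation time unit.
#'
#' @param pos numeric matrix (N x 2) of positions.
#' @param vel numeric matrix (N x 2) of velocities; defaults to zero.
#' @param species character vector (length N or 1) with values among
#'   `"fluid"`, `"wall"`, `"rbc"`, `"vwf"`, `"repulsive"`.
#' @param mass uniform particle mass (simulation mass units).
#' @param struct_id integer vector: structure id per particle
#'   (`NA` for unstructured fluid/wall particles).
#' @param bead_index integer vector: zero-based index of a bead within its
#'   structure (`NA` for fluid/wall).
#' @return object of class `particle_set`.
#' @export
particle_set <- function(pos, vel = NULL, species = "fluid", mass = 1,
                         struct_id = NULL, bead_index = NULL) {
  pos <- as.matrix(pos)
  if (ncol(pos) != 2L) stop("positions must be an N x 2 matrix")
  if (!all(is.finite(pos))) stop("positions must be finite")
  n <- nrow(pos)
  if (is.null(vel)) vel <- matrix(0, n, 2) else vel <- as.matrix(vel)
  if (!identical(dim(vel), dim(pos))) stop("velocity/position dimensions differ")
  if (length(species) == 1L) species <- rep(species, n)
  if (length(species) != n) stop("species must be assigned to every particle")
  code <- species_code(species)
  if (is.null(struct_id)) struct_id <- rep(NA_integer_, n)
  if (is.null(bead_index)) bead_index <- rep(NA_integer_, n)
  if (length(struct_id) != n || length(bead_index) != n)
    stop("array lengths must be identical across fields")
  structure(list(pos = unname(pos), vel = unname(vel), species = code,
                 mass = mass, struct_id = as.integer(struct_id),
                 bead_index = as.integer(bead_index)),
            class = "particle_set")
}

#' @export
print.particle_set <- function(x, ...) {
  tab <- table(species_label(x$species))
  cat("<particle_set> ", nrow(x$pos), " particles (",
      paste(names(tab), tab, sep = ":", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Number of particles in a particle set
#' @param x a [particle_set()].
#' @export
n_particles <- function(x) nrow(x$pos)

#' Concatenate particle sets
#'
#' Structure ids of later sets are shifted so they stay unique.
#' @param ... particle sets.
#' @export
bind_particles <- function(...) {
  sets <- list(...)
  sets <- sets[!vapply(sets, is.null, logical(1))]
  stopifnot(length(sets) > 0)
  offset <- 0L
  for (k in seq_along(sets)) {
    ids <- sets[[k]]$struct_id
    if (any(!is.na(ids))) {
      sets[[k]]$struct_id <- ids + offset
      offset <- offset + max(ids, na.rm = TRUE) + 1L
    }
  }
  out <- sets[[1L]]
  out$pos <- do.call(rbind, lapply(sets, `[[`, "pos"))
  out$vel <- do.call(rbind, lapply(sets, `[[`, "vel"))
  out$species <- unlist(lapply(sets, `[[`, "species"))
  out$struct_id <- unlist(lapply(sets, `[[`, "struct_id"))
  out$bead_index <- unlist(lapply(sets, `[[`, "bead_index"))
  out
}

#' DPD interaction parameters
#'
#' Parameters of the three DPD pair forces: conservative amplitude `a_cons`,
#' friction `gamma_dpd` and the random-force amplitude, which is tied to the
#' friction by the fluctuation-dissipation relation
#' `sigma_rand^2 = 2 * gamma_dpd * kBT`. The conservative weight is
#' `w(r) = 1 - r/r_c`; the random weight is `w_R = (1 - r/r_c)^s` with
#' `w_D = w_R^2` for the dissipative weight (`weight_exponent = s`; the
#' common soft-fluid choice is `s = 1`, `s = 0.25` gives a markedly more
#' viscous fluid).
#'
#' @param a_cons conservative amplitude (energy/length).
#' @param gamma_dpd friction coefficient (mass/time).
#' @param r_c interaction cutoff (micrometres).
#' @param kBT thermal energy (simulation energy units).
#' @param dt integration time step.
#' @param weight_exponent exponent `s` of the random-force weight.
#' @param gamma_fs friction for fluid-structure coupling (membrane vertices
#'   and chain beads couple to the solvent through the dissipative and
#'   random DPD forces only).
#' @param seed integer RNG seed for the pair random forces.
#' @return object of class `dpd_params`; `sigma_rand` is derived, not set.
#' @export
dpd_params <- function(a_cons = 25, gamma_dpd = 4.5, r_c = 1, kBT = 1,
                       dt = 0.005, weight_exponent = 1,
                       gamma_fs = 3 * gamma_dpd, seed = 1L) {
  if (r_c <= 0) stop("r_c must be > 0")
  if (dt <= 0) stop("dt must be > 0")
  if (kBT < 0) stop("kBT must be >= 0")
  if (gamma_dpd < 0 || gamma_fs < 0) stop("friction must be >= 0")
  structure(list(a_cons = a_cons, gamma_dpd = gamma_dpd,
                 sigma_rand = sqrt(2 * gamma_dpd * kBT), r_c = r_c,
                 kBT = kBT, dt = dt, weight_exponent = weight_exponent,
                 gamma_fs = gamma_fs, seed = as.integer(seed)),
            class = "dpd_params")
}

#' Simulation box
#'
#' A 2D box that is periodic along the flow axis (x) and either periodic or
#' wall-bounded along y. In channel mode exactly one axis (x) is periodic.
#'
#' @param length_x box length along the periodic flow axis (micrometres).
#' @param width_W channel width (micrometres).
#' @param periodic_y logical; `TRUE` gives a fully periodic box (no walls).
#' @export
box_spec <- function(length_x, width_W, periodic_y = FALSE) {
  if (length_x <= 0 || width_W <= 0) stop("box dimensions must be > 0")
  structure(list(length_x = length_x, width_W = width_W,
                 periodic_x = TRUE, periodic_y = periodic_y),
            class = "box_spec")
}

# assemble the flat system list consumed by the C++ engine
build_system <- function(particles, box, params,
                         rings = list(), chains = list(),
                         wall_pad = params$r_c,
                         sig_mem = 0.4, eps_mem = params$kBT,
                         sig_cross = 0.5, eps_cross = params$kBT,
                         sig_chain = 0.6, eps_chain = 4 * params$kBT) {
  list(species = particles$species,
       sid = ifelse(is.na(particles$struct_id), -1L, particles$struct_id),
       bidx = ifelse(is.na(particles$bead_index), 0L, particles$bead_index),
       mobile = particles$species != .SPECIES[["wall"]],
       Lx = box$length_x, W = box$width_W,
       per_x = box$periodic_x, per_y = box$periodic_y,
       ypad = if (box$periodic_y) 0 else wall_pad,
       mass = particles$mass,
       pair = list(a = params$a_cons, gamma = params$gamma_dpd,
                   s = params$weight_exponent, rc = params$r_c,
                   kBT = params$kBT, gamma_fs = params$gamma_fs,
                   sig_mem = sig_mem, eps_mem = eps_mem,
                   sig_cross = sig_cross, eps_cross = eps_cross,
                   sig_chain = sig_chain, eps_chain = eps_chain),
       rings = rings, chains = chains)
}
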