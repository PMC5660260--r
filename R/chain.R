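#' Polymer chain model parameters
#'
#' A VWF multimer (or repulsive control polymer) is a linear bead-spring
#' chain of `N` beads with harmonic bonds of equilibrium length `l_b` and a
#' Lennard-Jones pair interaction between non-bonded beads of the same
#' chain. In `"attractive"` (VWF) mode the full 12-6 LJ acts (cut at
#' `2.5 sigma`, energy-shifted); in `"repulsive"` mode the potential is
#' truncated at its minimum `2^(1/6) sigma` and shifted (a self-avoiding
#' polymer). `sigma = l_b`, the bead radius is `a_m = l_b / 2`, and the
#' contour length is `L_VWF = (N - 1) l_b`.
#'
#' @param N bead count (>= 2).
#' @param l_b equilibrium bond length (micrometres; 0.6 in 2D).
#' @param k_s harmonic bond stiffness in units of `kBT / a_m^2`.
#' @param epsilon LJ well depth in units of kBT (4 for VWF; the value that
#'   reproduces the experimentally observed critical shear rate for
#'   stretching).
#' @param mode `"attractive"` or `"repulsive"`.
#' @return object of class `chain_params` with derived `a_m`, `sigma`,
#'   `L_VWF`.
#' @export
chain_params <- function(N = 26L, l_b = 0.6, k_s = 400, epsilon = 4,
                         mode = c("attractive", "repulsive")) {
  mode <- match.arg(mode)
  if (N < 2L) stop("a chain needs at least 2 beads")
  a_m <- l_b / 2
  structure(list(N = as.integer(N), l_b = l_b, a_m = a_m,
                 k_s = k_s / a_m^2, sigma = l_b, epsilon = epsilon,
                 mode = mode, L_VWF = (N - 1) * l_b),
            class = "chain_params")
}

chain_entry <- function(params, start, kBT = 1) {
  list(start = as.integer(start - 1L), n = params$N,
       mode = if (params$mode == "attractive") 0L else 1L,
       ks = params$k_s * kBT, lb = params$l_b,
       sigma = params$sigma, eps = params$epsilon * kBT)
}

#' Contour length of a bead-spring chain
#'
#' `(N - 1) * l_b`: e.g. 15 um for N = 26 beads at `l_b` = 0.6 um.
#'
#' @param N bead count (>= 2).
#' @param l_b bond length (micrometres).
#' @export
contour_length <- function(N, l_b = 0.6) {
  if (any(N < 2)) stop("a chain needs at least 2 beads")
  (N - 1) * l_b
}

#' Build a polymer chain
#'
#' Beads along a straight line (`conformation = "straight"`) or wound into a
#' compact coil (`"coil"`, a hexagonal-spiral globule with bead spacing
#' `l_b`, the natural collapsed starting state for VWF).
#'
#' @param center chain centre-of-mass position.
#' @param params a [chain_params()].
#' @param conformation `"straight"` or `"coil"`.
#' @param orientation rotation (radians) applied to the conformation.
#' @param start 1-based index of the first bead in the assembled set.
#' @param kBT thermal energy scale for bond/LJ moduli.
#' @return list with `particles` (species `"vwf"` or `"repulsive"`) and
#'   `chain` (registry entry).
#' @export
build_chain <- function(center, params = chain_params(),
                        conformation = c("straight", "coil"),
                        orientation = 0, start = 1L, kBT = 1) {
  conformation <- match.arg(conformation)
  n <- params$N
  if (conformation == "straight") {
    xy <- cbind((seq_len(n) - (n + 1) / 2) * params$l_b, rep(0, n))
  } else {
    # Archimedean spiral walked in steps of l_b: bonds keep their
    # equilibrium length and successive turns stay ~sigma apart, so the
    # coil is compact without overlapping beads
    b <- 1.05 * params$sigma / (2 * pi)
    theta <- 0; r <- 0.55 * params$sigma
    xy <- matrix(0, n, 2)
    for (k in seq_len(n)) {
      xy[k, ] <- c(r * cos(theta), r * sin(theta))
      theta <- theta + params$l_b / max(r, 0.3 * params$sigma)
      r <- 0.55 * params$sigma + b * theta
    }
    xy <- sweep(xy, 2, colMeans(xy))
  }
  rot <- matrix(c(cos(orientation), sin(orientation),
                  -sin(orientation), cos(orientation)), 2, 2)
  xy <- xy %*% t(rot)
  xy <- sweep(xy, 2, center, "+")
  sp <- if (params$mode == "attractive") "vwf" else "repulsive"
  ps <- particle_set(xy, species = sp, struct_id = rep(0L, n),
                     bead_index = seq_len(n) - 1L)
  list(particles = ps, chain = chain_entry(params, start, kBT))
}

chain_indices <- function(chain, particles) {
  if (is.numeric(chain)) return(as.integer(chain))
  chain$start + seq_len(chain$n)
}

#' Chain bond forces
#'
#' Harmonic bond potential `U = k_s/2 (r - l_b)^2` per bond: axial,
#' equal-and-opposite forces, zero at `r = l_b`.
#'
#' @param chain chain registry entry from [build_chain()] (the `chain`
#'   element).
#' @param particles the assembled [particle_set()].
#' @param box optional [box_spec()].
#' @export
bond_forces <- function(chain, particles, box = NULL)
  chain_force_wrapper(chain, particles, box, "bond")

#' Intra-chain Lennard-Jones forces
#'
#' Pairwise LJ between non-bonded beads of the chain: full 12-6 with cutoff
#' `2.5 sigma` (shifted to zero there) in attractive mode; truncated at
#' `2^(1/6) sigma` and shifted (purely repulsive) in repulsive mode.
#' Directly bonded neighbours are excluded. Momentum conserving.
#'
#' @inheritParams bond_forces
#' @export
lj_pair_forces <- function(chain, particles, box = NULL)
  chain_force_wrapper(chain, particles, box, "lj")

chain_force_wrapper <- function(chain, particles, box, component) {
  if (is.null(box)) {
    ext <- 2 * (max(abs(particles$pos)) + 1)
    box <- box_spec(ext, ext)
  }
  params <- dpd_params()
  sys <- build_system(particles, box, params, chains = list(chain))
  cpp_forces(particles$pos, particles$vel, sys, params$dt, 0, 0, component)
}

#' Chain extension along an axis
#'
#' After unwrapping the bead coordinates along the periodic axis (walking
#' the bonds and accumulating minimum-image displacements), the extension
#' is `R_s = max - min` of the bead coordinates along the axis.
#'
#' @inheritParams bond_forces
#' @param axis 1 for the flow (x) axis, 2 for the wall-normal axis.
#' @return extension R_s (micrometres), bounded by the contour length plus
#'   a bead-diameter tolerance.
#' @export
chain_extension <- function(chain, particles, box = NULL, axis = 1L) {
  idx <- chain_indices(chain, particles)
  xy <- unwrap_coords(particles$pos[idx, , drop = FALSE], box)
  diff(range(xy[, axis]))
}

#' Radius of gyration of a chain
#'
#' Standard Rg about the unwrapped centre of mass.
#'
#' @inheritParams chain_extension
#' @export
radius_of_gyration <- function(chain, particles, box = NULL) {
  idx <- chain_indices(chain, particles)
  xy <- unwrap_coords(particles$pos[idx, , drop = FALSE], box)
  com <- colMeans(xy)
  sqrt(mean((xy[, 1] - com[1])^2 + (xy[, 2] - com[2])^2))
}

#' Single-chain shear-stretch scan
#'
#' Time-averaged relative extension `<R_s>/L_VWF` of a single chain in
#' unbounded simple shear, for a list of shear rates. The chain is evolved
#' with inertial Langevin dynamics coupled to a linear background flow
#' `v_x = gamma_dot * y` (free-draining solvent coupling). Starting from a
#' compact coil, the attractive (VWF) chain stays collapsed below a
#' critical shear rate and unfolds above it; a repulsive chain stretches
#' at much lower rates.
#'
#' @param chain_params a [chain_params()].
#' @param shear_rates numeric vector of shear rates (1/time).
#' @param duration total simulated time per shear rate.
#' @param seed RNG seed.
#' @param kBT thermal energy; `zeta` bead friction; `dt` time step.
#' @param warmup_frac fraction of the run discarded before averaging.
#' @param zeta bead friction coefficient.
#' @param dt integration time step.
#' @return data frame with columns `shear_rate`, `mean_extension`
#'   (`<R_s>/L_VWF`), `stderr`, `mean_rg`, `n_samples`, and a
#'   `short_duration` flag raised when the run is shorter than one
#'   tumbling period `2 pi / gamma_dot` at that shear rate.
#' @export
shear_stretch_scan <- function(chain_params, shear_rates, duration = 400,
                               seed = 1L, kBT = 1, zeta = 1, dt = 5e-4,
                               warmup_frac = 0.25) {
  built <- build_chain(c(0, 0), chain_params, conformation = "coil")
  pos0 <- built$particles$pos
  mode <- if (chain_params$mode == "attractive") 0L else 1L
  out <- lapply(shear_rates, function(g) {
    h <- if (g > 0) min(dt, 0.01 / g) else dt
    n_steps <- ceiling(duration / h)
    warmup <- ceiling(warmup_frac * n_steps)
    stride <- max(1L, floor((n_steps - warmup) / 400))
    res <- cpp_run_shear_chain(pos0, mode, chain_params$k_s * kBT,
                               chain_params$l_b, chain_params$sigma,
                               chain_params$epsilon * kBT, g, zeta, kBT, 1,
                               h, n_steps, warmup, stride, as.double(seed))
    rel <- res$Rs / chain_params$L_VWF
    neff <- max(1, length(rel) / 10)   # samples are correlated; deflate
    data.frame(shear_rate = g, mean_extension = mean(rel),
               stderr = sd(rel) / sqrt(neff), mean_rg = mean(res$Rg),
               n_samples = length(rel),
               short_duration = g > 0 && duration < 2 * pi / g)
  })
  res <- do.call(rbind, out)
  if (any(res$short_duration))
    warning("scan duration shorter than one tumbling period at the lowest shear rates")
  res
}
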