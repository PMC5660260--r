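#' Declarative fixture scenes
#'
#' A fixture scene is a declarative list of placed objects (straight chains,
#' tight globules, RBC rings, RBC wall lines) in a box, together with a
#' snapshot count. [generate_fixture()] realizes the scene as a static
#' trajectory and emits the analytically known observable values (P, Psi,
#' delta_CFL, R_s, COM positions) as ground truth, so every observable can
#' be tested without running the engine.
#'
#' @param L,W box dimensions (micrometres).
#' @param n_snapshots number of (identical) snapshots.
#' @param objects list of scene objects built with [fx_straight_chain()],
#'   [fx_tight_globule()], [fx_rbc_ring()], [fx_rbc_wall_line()].
#' @export
fixture_scene <- function(L = 30, W = 20, n_snapshots = 3L, objects = list()) {
  structure(list(L = L, W = W, n_snapshots = as.integer(n_snapshots),
                 objects = objects),
            class = "fixture_scene")
}

#' @describeIn fixture_scene a fully extended chain; every bead is active
#'   (interior angles are 180 degrees and non-bonded beads sit at least
#'   `2 l_b` apart).
#' @param N bead count; `l_b` bond length; `center` centre of mass;
#'   `orientation` angle to the flow axis; `mode` `"attractive"` or
#'   `"repulsive"`.
#' @param l_b bond length.
#' @param center object centre.
#' @param orientation rotation angle (radians).
#' @param mode chain species.
#' @export
fx_straight_chain <- function(N = 26L, l_b = 0.6, center = c(10, 10),
                              orientation = 0, mode = "attractive") {
  list(type = "straight_chain", N = as.integer(N), l_b = l_b,
       center = center, orientation = orientation, mode = mode)
}

#' @describeIn fixture_scene a chain wound onto a circle of diameter
#'   `0.8 * R_thres`, so every bead sees a non-bonded bead inside the
#'   activity radius: all beads are inactive by construction (needs
#'   N >= 4).
#' @param R_thres activity radius used to size the globule.
#' @export
fx_tight_globule <- function(N = 26L, l_b = 0.6, center = c(10, 10),
                             R_thres = 1.2 * l_b, mode = "attractive") {
  if (N < 4L) stop("tight globule needs N >= 4")
  list(type = "tight_globule", N = as.integer(N), l_b = l_b,
       center = center, R_thres = R_thres, mode = mode)
}

#' @describeIn fixture_scene a circular RBC ring of given radius.
#' @param radius ring radius; `N_v` vertex count.
#' @param N_v vertex count.
#' @export
fx_rbc_ring <- function(center = c(10, 10), radius = 2, N_v = 50L) {
  list(type = "rbc_ring", center = center, radius = radius,
       N_v = as.integer(N_v))
}

#' @describeIn fixture_scene a line of RBC membrane particles spanning the
#'   whole box length at a fixed distance from one wall (a degenerate flat
#'   core edge, synthetic by construction): the exact RBC-free-layer truth.
#' @param wall `"lower"` or `"upper"`; `dist` distance from that wall.
#' @param dist distance from the wall.
#' @param n_points points along the line (dense enough to fill every axial
#'   bin).
#' @export
fx_rbc_wall_line <- function(wall = c("lower", "upper"), dist = 2,
                             n_points = 400L) {
  wall <- match.arg(wall)
  list(type = "rbc_wall_line", wall = wall, dist = dist,
       n_points = as.integer(n_points))
}

#' Realize a fixture scene
#'
#' Builds the deterministic trajectory for a scene and the ground-truth
#' observable values implied by the construction. The truth values are
#' computed from the declared geometry directly (bead positions, layer
#' membership counts), independent of the observable implementations.
#'
#' @param scene a [fixture_scene()].
#' @param seed unused for static scenes; kept for interface uniformity.
#' @return list with `trajectory` and `truth` (fields `P` per chain
#'   species, `Psi` per species, `delta_cfl` per wall where defined,
#'   `R_s` and `active` per chain, `com` per structure).
#' @export
generate_fixture <- function(scene, seed = 1L) {
  L <- scene$L; W <- scene$W
  spec <- margination_spec(W = W)
  sets <- list(); rings <- list(); chains <- list()
  start <- 1L
  truth_chain <- list(); coms <- list()
  centers <- list(); radii <- c()
  wall_line_dists <- list(lower = c(), upper = c())
  any_ring <- FALSE
  for (ob in scene$objects) {
    if (ob$type %in% c("straight_chain", "tight_globule")) {
      if (ob$type == "straight_chain") {
        xy0 <- cbind((seq_len(ob$N) - (ob$N + 1) / 2) * ob$l_b, rep(0, ob$N))
        rot <- matrix(c(cos(ob$orientation), sin(ob$orientation),
                        -sin(ob$orientation), cos(ob$orientation)), 2, 2)
        xy <- sweep(xy0 %*% t(rot), 2, ob$center, "+")
        active <- rep(TRUE, ob$N)
        r_bound <- (ob$N - 1) * ob$l_b / 2
      } else {
        r <- 0.4 * ob$R_thres
        t <- seq(0, 2 * pi, length.out = ob$N + 1L)[seq_len(ob$N)]
        xy <- cbind(ob$center[1] + r * cos(t), ob$center[2] + r * sin(t))
        active <- rep(FALSE, ob$N)
        r_bound <- r
      }
      check_overlap(centers, radii, ob$center, r_bound)
      centers[[length(centers) + 1L]] <- ob$center; radii <- c(radii, r_bound)
      rs_truth <- diff(range(xy[, 1]))          # before wrapping
      act_in_layer <- sum(active &
        (xy[, 2] <= spec$delta_adhes | xy[, 2] >= W - spec$delta_adhes))
      sp <- if (ob$mode == "attractive") "vwf" else "repulsive"
      ps <- particle_set(cbind(xy[, 1] %% L, xy[, 2]), species = sp,
                         struct_id = rep(0L, ob$N),
                         bead_index = seq_len(ob$N) - 1L)
      cp <- chain_params(N = ob$N, l_b = ob$l_b, mode = ob$mode)
      ent <- chain_entry(cp, start)
      sets[[length(sets) + 1L]] <- ps
      chains[[length(chains) + 1L]] <- ent
      truth_chain[[length(truth_chain) + 1L]] <- list(
        species = sp, R_s = rs_truth, active = active,
        com = ob$center, act_in_layer = act_in_layer,
        in_delta = ob$center[2] <= spec$delta | ob$center[2] >= W - spec$delta,
        N = ob$N)
      coms[[length(coms) + 1L]] <- c(species = sp, y = ob$center[2])
      start <- start + ob$N
    } else if (ob$type == "rbc_ring") {
      any_ring <- TRUE
      check_overlap(centers, radii, ob$center, ob$radius)
      centers[[length(centers) + 1L]] <- ob$center
      radii <- c(radii, ob$radius)
      t <- seq(0, 2 * pi, length.out = ob$N_v + 1L)[seq_len(ob$N_v)]
      xy <- cbind((ob$center[1] + ob$radius * cos(t)) %% L,
                  ob$center[2] + ob$radius * sin(t))
      ps <- particle_set(xy, species = "rbc", struct_id = rep(0L, ob$N_v),
                         bead_index = seq_len(ob$N_v) - 1L)
      rp <- rbc_params(N_v = ob$N_v, L_0 = 2 * pi * ob$radius)
      sets[[length(sets) + 1L]] <- ps
      rings[[length(rings) + 1L]] <- ring_entry(rp, start)
      coms[[length(coms) + 1L]] <- c(species = "rbc", y = ob$center[2])
      start <- start + ob$N_v
    } else if (ob$type == "rbc_wall_line") {
      y <- if (ob$wall == "lower") ob$dist else W - ob$dist
      xy <- cbind(seq(0, L, length.out = ob$n_points + 1L)[seq_len(ob$n_points)],
                  rep(y, ob$n_points))
      ps <- particle_set(xy, species = "rbc",
                         struct_id = rep(0L, ob$n_points),
                         bead_index = seq_len(ob$n_points) - 1L)
      sets[[length(sets) + 1L]] <- ps
      wall_line_dists[[ob$wall]] <- c(wall_line_dists[[ob$wall]], ob$dist)
    } else stop("unknown scene object type '", ob$type, "'")
  }
  if (length(sets) == 0L) stop("empty scene")
  particles <- if (length(sets) == 1L) sets[[1L]] else do.call(bind_particles, sets)
  pos <- array(rep(particles$pos, scene$n_snapshots),
               dim = c(nrow(particles$pos), 2, scene$n_snapshots))
  traj <- trajectory(pos, times = seq_len(scene$n_snapshots),
                     species = particles$species,
                     struct_id = particles$struct_id,
                     bead_index = particles$bead_index,
                     box = box_spec(L, W), rings = rings, chains = chains,
                     meta = list(fixture = TRUE))
  # scene-level truths per chain species
  truth <- list(chains = truth_chain, spec = spec)
  for (sp in c("vwf", "repulsive")) {
    tc <- Filter(function(z) z$species == sp, truth_chain)
    if (length(tc) > 0) {
      truth$P[[sp]] <- mean(vapply(tc, `[[`, logical(1), "in_delta"))
      truth$Psi[[sp]] <- sum(vapply(tc, `[[`, numeric(1), "act_in_layer")) /
        sum(vapply(tc, `[[`, numeric(1), "N"))
    }
  }
  # the RBC-free-layer truth is exact only for wall-line scenes (full axial
  # coverage at a single height per wall)
  if (!any_ring &&
      (length(wall_line_dists$lower) + length(wall_line_dists$upper)) > 0) {
    heights <- c(wall_line_dists$lower, W - wall_line_dists$upper)
    truth$delta_cfl <- c(lower = min(heights), upper = W - max(heights))
  }
  truth$com_y <- do.call(rbind, lapply(coms, function(z)
    data.frame(species = z[["species"]], y = as.numeric(z[["y"]]))))
  list(trajectory = traj, truth = truth)
}

check_overlap <- function(centers, radii, center, r) {
  for (k in seq_along(centers)) {
    if (sqrt(sum((centers[[k]] - center)^2)) < radii[k] + r)
      stop("overlapping scene objects")
  }
  invisible(TRUE)
}
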