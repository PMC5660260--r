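#' Margination and adhesion-scoring parameters
#'
#' Thresholds used by the near-wall observables: the margination layer
#' `delta` (2 um, motivated by the range of potential VWF adhesion; the
#' choice scales the magnitude of margination probabilities but not their
#' ordering across conditions), the adhesive layer `delta_adhes` (1 um),
#' and the local-stretching activity criteria `R_thres = 1.2 l_b` and
#' `theta_thres = 130` degrees.
#'
#' @param delta margination layer thickness (micrometres).
#' @param delta_adhes adhesive near-wall layer thickness (micrometres).
#' @param l_b chain bond length used to scale `R_thres`.
#' @param R_thres neighbour-free radius for bead activity.
#' @param theta_thres minimum bond angle (degrees) for interior-bead
#'   activity.
#' @param W channel width (for the invariant `delta < W/2`).
#' @export
margination_spec <- function(delta = 2, delta_adhes = 1, l_b = 0.6,
                             R_thres = 1.2 * l_b, theta_thres = 130,
                             W = 20) {
  if (!(0 < delta_adhes && delta_adhes <= delta && delta < W / 2))
    stop("need 0 < delta_adhes <= delta < W/2")
  if (R_thres <= l_b) stop("R_thres must exceed l_b")
  structure(list(delta = delta, delta_adhes = delta_adhes, l_b = l_b,
                 R_thres = R_thres, theta_thres = theta_thres, W = W),
            class = "margination_spec")
}

#' Centre-of-mass distribution across the channel
#'
#' Per-snapshot COM of every structure of the species, binned across the
#' wall-normal coordinate as a normalized probability density (integrates
#' to 1). Both halves can be folded onto `[0, W/2]` by symmetry.
#'
#' @param traj a [trajectory()].
#' @param species `"rbc"`, `"vwf"`, `"repulsive"` (or several).
#' @param n_bins number of bins.
#' @param fold fold the two channel halves together.
#' @return data frame with `y` (bin centre), `density`, `count`.
#' @export
com_distribution <- function(traj, species = "vwf", n_bins = 40L,
                             fold = FALSE) {
  W <- traj$box$width_W
  ys <- com_heights(traj, species)
  if (fold) {
    ys <- ifelse(ys > W / 2, W - ys, ys)
    breaks <- seq(0, W / 2, length.out = n_bins + 1L)
  } else {
    breaks <- seq(0, W, length.out = n_bins + 1L)
  }
  h <- hist(ys, breaks = breaks, plot = FALSE)
  data.frame(y = h$mids, density = h$density, count = h$counts)
}

# wall-normal COM coordinates of all structures of the species, all frames
com_heights <- function(traj, species) {
  codes <- species_code(species)
  entries <- c(traj$rings, traj$chains)
  keep <- vapply(entries, function(e)
    traj$species[e$start + 1L] %in% codes, logical(1))
  if (!any(keep)) stop("no structures of species ",
                       paste(species, collapse = "/"), " in the trajectory")
  nf <- n_frames(traj)
  unlist(lapply(entries[keep], function(e)
    vapply(seq_len(nf), function(f) struct_com(traj, f, e)[2], numeric(1))))
}

#' RBC-free-layer thickness
#'
#' Distance from each wall to the edge of the RBC core: per snapshot and
#' per axial bin (default width `D_r / 2`), the distance from the wall to
#' the nearest RBC membrane particle, averaged over bins, snapshots and
#' (for the scalar result) both walls. Without RBCs the thickness is
#' defined as `W/2` and flagged.
#'
#' @param traj a [trajectory()].
#' @param bin_width axial bin width (micrometres).
#' @return list with `delta_cfl` (scalar mean), `per_wall` (named lower /
#'   upper means) and `no_core` flag.
#' @export
rbc_free_layer <- function(traj, bin_width = NULL) {
  W <- traj$box$width_W
  rbc_code <- species_code("rbc")
  idx <- which(traj$species == rbc_code)
  if (length(idx) == 0L)
    return(list(delta_cfl = W / 2, per_wall = c(lower = W / 2, upper = W / 2),
                no_core = TRUE))
  if (is.null(bin_width)) bin_width <- 19.22 / pi / 2
  L <- traj$box$length_x
  n_bins <- max(1L, round(L / bin_width))
  nf <- n_frames(traj)
  lower <- matrix(NA_real_, nf, n_bins)
  upper <- matrix(NA_real_, nf, n_bins)
  for (f in seq_len(nf)) {
    x <- traj$pos[idx, 1, f] %% L
    y <- traj$pos[idx, 2, f]
    bin <- pmin(floor(x / L * n_bins) + 1L, n_bins)
    lo <- tapply(y, factor(bin, levels = seq_len(n_bins)), min)
    hi <- tapply(W - y, factor(bin, levels = seq_len(n_bins)), min)
    lower[f, ] <- ifelse(is.na(lo), W / 2, lo)     # empty axial bin: no core
    upper[f, ] <- ifelse(is.na(hi), W / 2, hi)
  }
  per_wall <- c(lower = mean(lower), upper = mean(upper))
  list(delta_cfl = mean(per_wall), per_wall = per_wall, no_core = FALSE)
}

#' Margination probability
#'
#' Probability of a chain's centre of mass to be within a distance `delta`
#' of either wall: the fraction of chain-snapshots whose COM lies in the
#' near-wall layer, with a bootstrap standard error over snapshots.
#'
#' @param traj a [trajectory()] with at least one chain.
#' @param spec a [margination_spec()].
#' @param species which chains to score (`"vwf"`, `"repulsive"`, or both).
#' @param n_boot bootstrap resamples for the standard error.
#' @param seed bootstrap RNG seed.
#' @return list with `P`, `stderr`, `n_obs`.
#' @export
margination_probability <- function(traj, spec = margination_spec(W = traj$box$width_W),
                                    species = "vwf", n_boot = 200L, seed = 1L) {
  W <- traj$box$width_W
  coms <- chain_coms(traj, species)
  if (nrow(coms) < 1L) stop("no chain snapshots")
  near <- coms$y <= spec$delta | coms$y >= W - spec$delta
  P <- mean(near)
  # bootstrap over frames (snapshots are the exchangeable unit)
  frames <- split(near, coms$frame)
  bs <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    mean(unlist(frames[sample.int(length(frames), replace = TRUE)]))
  }, numeric(1)))
  list(P = P, stderr = sd(bs), n_obs = nrow(coms))
}

#' Regional chain extension
#'
#' Assigns every chain-snapshot to the RBC-free layer (COM within
#' `delta_cfl` of either wall) or to the flow core, and reports the mean
#' and distribution of the flow-direction extension `R_s`, normalized by
#' the contour length. Regions with zero samples are flagged, not
#' zero-filled.
#'
#' @param traj a [trajectory()].
#' @param delta_cfl RBC-free-layer thickness (time-averaged scalar, e.g.
#'   from [rbc_free_layer()]).
#' @param L_VWF contour length used for normalization (defaults to the
#'   first scored chain's).
#' @param species which chains to score.
#' @param n_bins histogram bins for the extension distributions.
#' @param assignment `"mean"` assigns a chain-snapshot to the free layer if
#'   its COM is within the time-averaged `delta_cfl` of either wall;
#'   `"instantaneous"` compares against the local instantaneous core edge
#'   instead (the distance from the wall to the nearest RBC vertex in the
#'   chain's axial bin at that snapshot), which resolves chains sitting in
#'   local pockets of the fluctuating core edge.
#' @param bin_width axial bin width for the instantaneous core edge.
#' @return object of class `regional_stretch`: per-region mean relative
#'   extension, sample counts, normalized histograms, and flags.
#' @export
regional_stretch <- function(traj, delta_cfl, L_VWF = NULL,
                             species = "vwf", n_bins = 20L,
                             assignment = c("mean", "instantaneous"),
                             bin_width = NULL) {
  assignment <- match.arg(assignment)
  W <- traj$box$width_W
  codes <- species_code(species)
  keep <- which(vapply(traj$chains, function(ch)
    traj$species[ch$start + 1L] %in% codes, logical(1)))
  if (length(keep) == 0L) stop("no chains of the requested species")
  if (is.null(L_VWF)) {
    ch <- traj$chains[[keep[1]]]
    L_VWF <- (ch$n - 1) * ch$lb
  }
  nf <- n_frames(traj)
  obs <- do.call(rbind, lapply(keep, function(k) {
    e <- traj$chains[[k]]
    t(vapply(seq_len(nf), function(f) {
      idx <- e$start + seq_len(e$n)
      xy <- unwrap_coords(traj$pos[idx, , f, drop = TRUE], traj$box)
      c(rs = diff(range(xy[, 1])), ycom = mean(xy[, 2]),
        xcom = mean(xy[, 1]) %% traj$box$length_x, frame = f)
    }, numeric(4)))
  }))
  if (assignment == "mean") {
    in_fl <- obs[, "ycom"] <= delta_cfl | obs[, "ycom"] >= W - delta_cfl
  } else {
    if (is.null(bin_width)) bin_width <- 19.22 / pi / 2
    L <- traj$box$length_x
    n_ax <- max(1L, round(L / bin_width))
    rbc_idx <- which(traj$species == species_code("rbc"))
    in_fl <- vapply(seq_len(nrow(obs)), function(r) {
      f <- obs[r, "frame"]
      wall_dist <- min(obs[r, "ycom"], W - obs[r, "ycom"])
      if (length(rbc_idx) == 0L) return(wall_dist <= W / 2)
      bin_q <- pmin(floor(obs[r, "xcom"] / L * n_ax) + 1L, n_ax)
      x <- traj$pos[rbc_idx, 1, f] %% L
      y <- traj$pos[rbc_idx, 2, f]
      sel <- pmin(floor(x / L * n_ax) + 1L, n_ax) == bin_q
      if (!any(sel)) return(TRUE)          # no core locally
      edge <- if (obs[r, "ycom"] <= W / 2) min(y[sel]) else min(W - y[sel])
      wall_dist <= edge
    }, logical(1))
  }
  breaks <- seq(0, 1.1, length.out = n_bins + 1L)
  region_stats <- function(sel) {
    if (!any(sel)) return(list(mean = NA_real_, n = 0L, hist = NULL, empty = TRUE))
    rel <- pmin(obs[sel, "rs"] / L_VWF, 1.1)
    h <- hist(rel, breaks = breaks, plot = FALSE)
    list(mean = mean(rel), n = sum(sel),
         hist = data.frame(mid = h$mids, density = h$density), empty = FALSE)
  }
  structure(list(fl = region_stats(in_fl), core = region_stats(!in_fl),
                 L_VWF = L_VWF, delta_cfl = delta_cfl),
            class = "regional_stretch")
}

#' Bead adhesion activity
#'
#' A chain bead is active — its adhesive sites exposed by local stretching
#' — if (a) no non-bonded bead of the same chain lies within `R_thres` of
#' it, and (b) for interior beads, the angle between its two bonds exceeds
#' `theta_thres`; end beads are scored on (a) only.
#'
#' @param xy unwrapped bead coordinates of a single chain (N x 2, N >= 2).
#' @param spec a [margination_spec()].
#' @return logical vector of per-bead activity flags.
#' @export
bead_activity <- function(xy, spec = margination_spec()) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 2L) stop("a chain needs at least 2 beads")
  d <- as.matrix(dist(xy))
  active <- logical(n)
  for (i in seq_len(n)) {
    nb <- setdiff(which(d[i, ] < spec$R_thres), c(i - 1L, i, i + 1L))
    cond_a <- length(nb) == 0L
    if (i == 1L || i == n) {
      active[i] <- cond_a
    } else {
      b1 <- xy[i, ] - xy[i - 1L, ]
      b2 <- xy[i + 1L, ] - xy[i, ]
      ang <- 180 - abs(atan2(b1[1] * b2[2] - b1[2] * b2[1],
                             sum(b1 * b2))) * 180 / pi
      active[i] <- cond_a && (ang > spec$theta_thres)
    }
  }
  active
}

#' Potential-adhesion probability
#'
#' `Psi = sum_i N_act^i / (N_tot * N_time)`: per snapshot, the number of
#' chain beads that are both active (locally stretched, [bead_activity()])
#' and within the adhesive layer `delta_adhes` of either wall, summed over
#' snapshots and normalized by the total number of chain beads and the
#' number of snapshots. Margination and stretching are both preconditions
#' for adhesion; Psi scores their convolution.
#'
#' @param traj a [trajectory()] with chains.
#' @param spec a [margination_spec()].
#' @param species which chains to score.
#' @return list with `Psi`, `N_tot`, `N_time`.
#' @export
adhesion_potential <- function(traj, spec = margination_spec(W = traj$box$width_W),
                               species = "vwf") {
  W <- traj$box$width_W
  codes <- species_code(species)
  keep <- which(vapply(traj$chains, function(ch)
    traj$species[ch$start + 1L] %in% codes, logical(1)))
  if (length(keep) == 0L) stop("no chains of the requested species")
  nf <- n_frames(traj)
  N_tot <- sum(vapply(traj$chains[keep], `[[`, integer(1), "n"))
  count <- 0
  for (f in seq_len(nf)) {
    for (k in keep) {
      e <- traj$chains[[k]]
      idx <- e$start + seq_len(e$n)
      xy <- unwrap_coords(traj$pos[idx, , f, drop = TRUE], traj$box)
      act <- bead_activity(xy, spec)
      ywrap <- traj$pos[idx, 2, f]
      near <- ywrap <= spec$delta_adhes | ywrap >= W - spec$delta_adhes
      count <- count + sum(act & near)
    }
  }
  list(Psi = count / (N_tot * nf), N_tot = N_tot, N_time = nf)
}
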