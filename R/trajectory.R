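#' Trajectory container
#'
#' Time-ordered snapshots of particle positions (and optionally velocities)
#' plus box metadata and the structure registry; the interchange object
#' between the engine, the file I/O and the observables.
#'
#' @param pos numeric array `(N, 2, n_frames)`.
#' @param vel matching velocity array or `NULL`.
#' @param times snapshot times.
#' @param species integer species codes (length N).
#' @param struct_id integer structure ids (NA for fluid/wall).
#' @param bead_index zero-based in-structure bead indices.
#' @param box a [box_spec()].
#' @param rings,chains registry entries of the structures.
#' @param meta named list of run metadata.
#' @export
trajectory <- function(pos, vel = NULL, times = NULL, species, struct_id,
                       bead_index, box, rings = list(), chains = list(),
                       meta = list()) {
  stopifnot(length(dim(pos)) == 3L, dim(pos)[2] == 2L)
  if (is.null(times)) times <- seq_len(dim(pos)[3])
  structure(list(pos = pos, vel = vel, times = times, species = species,
                 struct_id = struct_id, bead_index = bead_index, box = box,
                 rings = rings, chains = chains, meta = meta),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", dim(x$pos)[1], " particles, ", n_frames(x),
      " frames, box ", signif(x$box$length_x, 4), " x ",
      signif(x$box$width_W, 4), " um, ", length(x$rings), " RBCs, ",
      length(x$chains), " chains\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()].
#' @export
n_frames <- function(traj) dim(traj$pos)[3]

#' Extract one frame as a particle set
#' @param traj a [trajectory()].
#' @param frame frame index.
#' @export
get_frame <- function(traj, frame) {
  v <- if (!is.null(traj$vel) && length(traj$vel) > 0)
    traj$vel[, , frame] else NULL
  particle_set(traj$pos[, , frame], vel = v,
               species = species_label(traj$species),
               struct_id = traj$struct_id, bead_index = traj$bead_index)
}

# unwrapped centre of mass of a contiguous structure in one frame
struct_com <- function(traj, frame, entry) {
  idx <- entry$start + seq_len(entry$n)
  xy <- unwrap_coords(traj$pos[idx, , frame, drop = TRUE], traj$box)
  com <- colMeans(xy)
  com[1] <- com[1] %% traj$box$length_x
  com
}

# matrix of chain COMs: rows = chain-frame observations
chain_coms <- function(traj, species = c("vwf", "repulsive")) {
  codes <- species_code(species)
  keep <- which(vapply(traj$chains, function(ch)
    traj$species[ch$start + 1L] %in% codes, logical(1)))
  if (length(keep) == 0L) stop("no chains of species ",
                               paste(species, collapse = "/"), " present")
  nf <- n_frames(traj)
  out <- do.call(rbind, lapply(keep, function(k) {
    t(vapply(seq_len(nf), function(f) struct_com(traj, f, traj$chains[[k]]),
             numeric(2)))
  }))
  data.frame(chain = rep(keep, each = nf), frame = rep(seq_len(nf), length(keep)),
             x = out[, 1], y = out[, 2])
}
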