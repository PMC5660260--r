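#' Parse a run configuration file
#'
#' Reads a YAML configuration, validates every field against its
#' invariants, rejects unknown keys (with a nearest-match suggestion) and
#' materializes all defaults explicitly. The returned object is a full
#' [channel_config()].
#'
#' @param path path to a YAML configuration file.
#' @return a [channel_config()] with attribute `"materialized"` listing
#'   every parameter value actually in effect.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(channel_config))
  rbc_known <- names(formals(rbc_params))
  chain_known <- names(formals(chain_params))
  check_keys <- function(keys, known, where) {
    bad <- setdiff(keys, known)
    for (b in bad) {
      sug <- known[which.min(utils::adist(b, known))]
      stop("unknown ", where, " key '", b, "'; did you mean '", sug, "'?")
    }
  }
  check_keys(names(raw), known, "config")
  if (!is.null(raw$rbc)) {
    check_keys(names(raw$rbc), rbc_known, "rbc")
    raw$rbc <- do.call(rbc_params, raw$rbc)
  }
  if (!is.null(raw$chain)) {
    check_keys(names(raw$chain), chain_known, "chain")
    raw$chain <- do.call(chain_params, raw$chain)
  }
  cfg <- do.call(channel_config, raw)
  attr(cfg, "materialized") <- unclass(cfg)
  cfg
}

#' Write a trajectory as extended XYZ
#'
#' One frame per snapshot: an atom count line, a comment line carrying the
#' box (`Lattice=...`), the column layout (`Properties=...`), `Time=` and a
#' structure-registry reference, then one line per particle with species
#' label, position (z = 0), velocity, structure id and bead index. The
#' registry itself is stored as a JSON sidecar `<path>.registry.json` so a
#' round trip restores the full trajectory object.
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @export
write_trajectory <- function(traj, path) {
  n <- dim(traj$pos)[1]
  nf <- n_frames(traj)
  lab <- species_label(traj$species)
  sid <- ifelse(is.na(traj$struct_id), -1L, traj$struct_id)
  bidx <- ifelse(is.na(traj$bead_index), -1L, traj$bead_index)
  con <- file(path, "w")
  on.exit(close(con))
  has_vel <- !is.null(traj$vel) && length(traj$vel) > 0
  props <- if (has_vel)
    "Properties=species:S:1:pos:R:3:velo:R:3:struct:I:1:bead:I:1"
  else "Properties=species:S:1:pos:R:3:struct:I:1:bead:I:1"
  for (f in seq_len(nf)) {
    writeLines(as.character(n), con)
    writeLines(sprintf(
      'Lattice="%.10g 0 0 0 %.10g 0 0 0 1" %s Time=%.10g Registry=%s',
      traj$box$length_x, traj$box$width_W, props, traj$times[f],
      basename(paste0(path, ".registry.json"))), con)
    if (has_vel) {
      writeLines(sprintf("%s %.10g %.10g 0 %.10g %.10g 0 %d %d",
                         lab, traj$pos[, 1, f], traj$pos[, 2, f],
                         traj$vel[, 1, f], traj$vel[, 2, f], sid, bidx), con)
    } else {
      writeLines(sprintf("%s %.10g %.10g 0 %d %d",
                         lab, traj$pos[, 1, f], traj$pos[, 2, f], sid, bidx),
                 con)
    }
  }
  jsonlite::write_json(
    list(rings = traj$rings, chains = traj$chains,
         periodic_y = traj$box$periodic_y),
    paste0(path, ".registry.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an extended-XYZ trajectory
#'
#' Inverse of [write_trajectory()]; coordinates are restored to output
#' precision. Malformed frames raise an error naming the frame index.
#'
#' @param path file path.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  reg_path <- paste0(path, ".registry.json")
  registry <- if (file.exists(reg_path)) jsonlite::read_json(reg_path)
              else list(rings = list(), chains = list(), periodic_y = FALSE)
  fix_entry <- function(e) lapply(e, function(v) if (is.list(v)) unlist(v) else v)
  rings <- lapply(registry$rings, fix_entry)
  chains <- lapply(registry$chains, fix_entry)
  pos <- list(); vel <- list(); times <- c()
  i <- 1L; f <- 0L
  box <- NULL; species <- NULL; sid <- NULL; bidx <- NULL
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i]))
      stop("malformed frame header at frame ", f + 1L)
    n <- as.integer(lines[i])
    f <- f + 1L
    comment <- lines[i + 1L]
    lat <- regmatches(comment, regexec('Lattice="([^"]+)"', comment))[[1]][2]
    latv <- as.numeric(strsplit(trimws(lat), "\\s+")[[1]])
    tm <- regmatches(comment, regexec("Time=([-0-9.eE+]+)", comment))[[1]][2]
    times <- c(times, as.numeric(tm))
    has_vel <- grepl("velo:R:3", comment)
    if (i + 1L + n > length(lines)) stop("truncated frame ", f)
    body <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(body), "\\s+")
    ncol_expect <- if (has_vel) 9L else 6L
    if (any(lengths(toks) != ncol_expect))
      stop("malformed atom line in frame ", f)
    mat <- matrix(unlist(toks), nrow = n, byrow = TRUE)
    if (f == 1L) {
      box <- box_spec(latv[1], latv[5],
                      periodic_y = isTRUE(registry$periodic_y))
      species <- species_code(mat[, 1])
      sid <- as.integer(mat[, ncol_expect - 1L])
      sid[sid < 0] <- NA_integer_
      bidx <- as.integer(mat[, ncol_expect])
      bidx[bidx < 0] <- NA_integer_
    } else if (n != length(species)) {
      stop("frame ", f, " atom count mismatch")
    }
    pos[[f]] <- cbind(as.numeric(mat[, 2]), as.numeric(mat[, 3]))
    if (has_vel) vel[[f]] <- cbind(as.numeric(mat[, 5]), as.numeric(mat[, 6]))
    i <- i + 2L + n
  }
  if (f == 0L)
    stop("empty trajectory file")
  np <- length(species)
  pos_arr <- array(unlist(pos), dim = c(np, 2, f))
  vel_arr <- if (length(vel)) array(unlist(vel), dim = c(np, 2, f)) else NULL
  trajectory(pos_arr, vel = vel_arr, times = times, species = species,
             struct_id = sid, bead_index = bidx, box = box,
             rings = rings, chains = chains)
}

#' Run manifest
#'
#' Metadata making a run's published numbers traceable: configuration
#' hash, seed, package version, realized hematocrit, measured flow
#' quantities and snapshot count.
#'
#' @param config a [channel_config()].
#' @param H_t_realized realized RBC area fraction.
#' @param res raw engine result (internal).
#' @export
run_manifest <- function(config, H_t_realized, res = NULL) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(unclass(config)[order(names(unclass(config)))], tf)
  list(config_hash = unname(tools::md5sum(tf)),
       seed = config$seed,
       version = as.character(utils::packageVersion("vwfmarg")),
       H_t = config$H_t, H_t_realized = H_t_realized,
       n_frames = if (!is.null(res)) res$n_frames else NA,
       kBT_measured = if (!is.null(res)) mean(tail(res$temp_trace,
         max(1L, length(res$temp_trace) %/% 2))) else NA,
       vbar_trace = if (!is.null(res)) res$vbar_trace else NULL,
       wall_correction = if (!is.null(res))
         c(lower = tail(res$corr_lo, 1), upper = tail(res$corr_hi, 1))
       else NULL,
       timestamp = format(Sys.time(), tz = "UTC"))
}

#' Write an observable table as CSV with a metadata header
#'
#' Every CSV output carries the parameters needed to recompute it as
#' `# key: value` comment lines before the table.
#'
#' @param df data frame.
#' @param path output path.
#' @param meta named list written as header comments.
#' @export
write_result_csv <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, paste(format(meta[[k]]), collapse = " ")), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
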