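# shared builders for small test systems

# random fluid particle set in a box
random_fluid <- function(n, Lx, Ly, seed = 1) {
  with_seed_test(seed, particle_set(cbind(runif(n, 0, Lx), runif(n, 0, Ly))))
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

# O(N^2) reference pair list with minimum image in x (and optionally y)
brute_pairs <- function(pos, rc, Lx, Ly, per_y = FALSE) {
  n <- nrow(pos)
  out <- list()
  for (i in seq_len(n - 1)) {
    dx <- abs(pos[i, 1] - pos[(i + 1):n, 1])
    dx <- pmin(dx, Lx - dx)
    dy <- abs(pos[i, 2] - pos[(i + 1):n, 2])
    if (per_y) dy <- pmin(dy, Ly - dy)
    j <- which(dx^2 + dy^2 < rc^2)
    if (length(j)) out[[length(out) + 1L]] <- cbind(i, i + j)
  }
  m <- do.call(rbind, out)
  if (is.null(m)) matrix(integer(), 0, 2) else m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# central-difference gradient of a scalar energy function of an N x 2
# coordinate matrix
fd_gradient <- function(energy_fn, pos, h = 1e-5, rows = seq_len(nrow(pos))) {
  g <- matrix(NA_real_, nrow(pos), 2)
  for (i in rows) {
    for (d in 1:2) {
      p1 <- pos; p1[i, d] <- p1[i, d] + h
      p2 <- pos; p2[i, d] <- p2[i, d] - h
      g[i, d] <- (energy_fn(p1) - energy_fn(p2)) / (2 * h)
    }
  }
  g
}

# perturbed RBC ring plus its energy evaluator for one component
make_test_ring <- function(seed = 2, spring_form = "wlc", sd = 0.02) {
  rp <- rbc_params(spring_form = spring_form)
  built <- build_rbc(c(10, 10), rp, shape = "biconcave")
  ps <- built$particles
  ps$pos <- ps$pos + with_seed_test(seed, matrix(rnorm(2 * rp$N_v, sd = sd),
                                                ncol = 2))
  list(ps = ps, ring = built$ring, params = rp,
       box = box_spec(40, 40))
}

ring_energy_fn <- function(ring, box, component) {
  params <- dpd_params()
  function(pos) {
    ps <- particle_set(pos, species = "rbc",
                       struct_id = rep(0L, nrow(pos)),
                       bead_index = seq_len(nrow(pos)) - 1L)
    attr(system_energy(ps, params, box, components = component,
                       rings = list(ring)), "total")
  }
}

make_test_chain <- function(seed = 3, mode = "attractive", sd = 0.05,
                            conformation = "coil") {
  cp <- chain_params(mode = mode)
  built <- build_chain(c(5, 5), cp, conformation = conformation)
  ps <- built$particles
  ps$pos <- ps$pos + with_seed_test(seed, matrix(rnorm(2 * cp$N, sd = sd),
                                                ncol = 2))
  list(ps = ps, chain = built$chain, params = cp, box = box_spec(40, 40))
}

# drive the compiled integrator on a fully periodic box (no walls)
run_periodic_box <- function(ps, box, params, n_steps, warmup, stride = 100,
                             record = TRUE) {
  sys <- vwfmarg:::build_system(ps, box, params)
  ctrl <- list(dt = params$dt, seed = as.double(params$seed),
               n_steps = as.double(n_steps), warmup = as.double(warmup),
               stride = as.double(stride), g = 0, bounce = FALSE,
               adaptive = FALSE, k_gain = 0, interval = 100,
               record = record, record_vel = TRUE, damp = 0, fcap = 0,
               temp_tol = 1, temp_action = 0L, check_every = 50)
  vwfmarg:::cpp_run_channel(ps$pos, ps$vel, sys, ctrl)
}

chain_energy_fn <- function(chain, box, component) {
  params <- dpd_params()
  function(pos) {
    ps <- particle_set(pos, species = "vwf",
                       struct_id = rep(0L, nrow(pos)),
                       bead_index = seq_len(nrow(pos)) - 1L)
    attr(system_energy(ps, params, box, components = component,
                       chains = list(chain)), "total")
  }
}

# session tempdir is cleaned up automatically at exit
withr_local_tempfile <- function(ext) tempfile(fileext = ext)
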