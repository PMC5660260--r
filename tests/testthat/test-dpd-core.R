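# DPD engine primitives: neighbour search, pair forces, integrator,
# temperature diagnostics

test_that("neighbour list finds direct and periodic-image pairs", {
  box <- box_spec(10, 8)
  ps <- particle_set(rbind(c(2, 4), c(2.5, 4)))
  expect_equal(nrow(build_neighbor_list(ps, 1, box)), 1L)

  # pair across the periodic x boundary
  ps2 <- particle_set(rbind(c(0.1, 4), c(9.9, 4)))
  nl <- build_neighbor_list(ps2, 1, box)
  expect_equal(unname(nl), cbind(1L, 2L))

  # beyond cutoff: nothing
  ps3 <- particle_set(rbind(c(2, 4), c(3.5, 4)))
  expect_equal(nrow(build_neighbor_list(ps3, 1, box)), 0L)

  expect_error(build_neighbor_list(ps, -1, box), "r_c")
})

test_that("neighbour list equals all-pairs brute force on random configurations", {
  for (seed in 1:3) {
    ps <- random_fluid(100, 10, 8, seed = seed)
    box <- box_spec(10, 8)
    nl <- build_neighbor_list(ps, 1, box)
    ref <- brute_pairs(ps$pos, 1, 10, 8)
    expect_equal(unname(nl), unname(ref))
  }
  # fully periodic box
  ps <- random_fluid(80, 6, 6, seed = 9)
  box <- box_spec(6, 6, periodic_y = TRUE)
  expect_equal(unname(build_neighbor_list(ps, 1, box)),
               unname(brute_pairs(ps$pos, 1, 6, 6, per_y = TRUE)))
})

test_that("conservative force is repulsive, equal and opposite, and forces sum to zero", {
  box <- box_spec(10, 10, periodic_y = TRUE)
  params <- dpd_params(kBT = 1)
  ps <- particle_set(rbind(c(5, 5), c(5.5, 5)))
  f <- dpd_pair_forces(ps, params, box, components = "conservative")
  expect_equal(f[1, ], -f[2, ])            # Newton's third law
  expect_lt(f[1, 1], 0)                    # particle 1 pushed to -x
  expect_equal(f[1, 2], 0)
  expect_equal(abs(f[1, 1]), params$a_cons * 0.5)  # a * (1 - r/rc)

  # any configuration: vector sum of all pair forces vanishes
  ps2 <- random_fluid(60, 10, 10, seed = 4)
  ps2 <- thermal_velocities(ps2, 1, seed = 5)
  f2 <- dpd_pair_forces(ps2, params, box,
                        components = c("conservative", "dissipative", "random"))
  expect_equal(colSums(f2), c(0, 0), tolerance = 1e-12)
})

test_that("fluctuation-dissipation relation is built into the parameters", {
  p <- dpd_params(gamma_dpd = 4.5, kBT = 0.5)
  expect_equal(p$sigma_rand^2, 2 * 4.5 * 0.5)
  expect_error(dpd_params(r_c = 0), "r_c")
  expect_error(dpd_params(dt = -1), "dt")
})

test_that("pair random forces are keyed by (seed, step, pair): reproducible and step-dependent", {
  box <- box_spec(10, 10, periodic_y = TRUE)
  params <- dpd_params(seed = 7)
  ps <- random_fluid(40, 10, 10, seed = 11)
  f1 <- dpd_pair_forces(ps, params, box, step = 3, components = "random")
  f2 <- dpd_pair_forces(ps, params, box, step = 3, components = "random")
  expect_identical(f1, f2)                       # deterministic replay
  f3 <- dpd_pair_forces(ps, params, box, step = 4, components = "random")
  expect_false(isTRUE(all.equal(f1, f3)))        # fresh draws each step
  params2 <- dpd_params(seed = 8)
  f4 <- dpd_pair_forces(ps, params2, box, step = 3, components = "random")
  expect_false(isTRUE(all.equal(f1, f4)))        # seed enters the stream
})

test_that("velocity-Verlet: free drift, dt = 0 identity, oscillator energy drift", {
  ps <- particle_set(rbind(c(0, 0)), vel = rbind(c(0.3, -0.2)))
  zero_f <- function(p, s) matrix(0, n_particles(p), 2)
  out <- velocity_verlet_step(ps, zero_f, dt = 0.1)
  expect_equal(out$pos[1, ], c(0.03, -0.02))
  expect_identical(velocity_verlet_step(ps, zero_f, dt = 0), ps)

  # harmonic oscillator: k = m = 1, period 2*pi; dt = 0.001 of the period
  spring_f <- function(p, s) -p$pos
  ps <- particle_set(rbind(c(1, 0)))
  dt <- 0.001 * 2 * pi
  e0 <- 0.5 * sum(ps$pos^2) + 0.5 * sum(ps$vel^2)
  for (i in seq_len(1000)) ps <- velocity_verlet_step(ps, spring_f, dt)
  e1 <- 0.5 * sum(ps$pos^2) + 0.5 * sum(ps$vel^2)
  expect_lt(abs(e1 - e0) / e0, 1e-4)
})

test_that("frozen wall particles never move", {
  ps <- particle_set(rbind(c(1, 1), c(2, 2)), species = c("wall", "fluid"),
                     vel = rbind(c(1, 1), c(1, 1)))
  out <- velocity_verlet_step(ps, function(p, s) matrix(1, 2, 2), dt = 0.1)
  expect_equal(out$pos[1, ], c(1, 1))
  expect_false(isTRUE(all.equal(out$pos[2, ], c(2, 2))))
})

test_that("kinetic temperature: zeros, seeded Maxwell draw, Galilean invariance", {
  ps <- particle_set(matrix(runif(200), 100, 2))
  expect_equal(kinetic_temperature(ps, drift_removal = FALSE), 0)

  n <- 4000
  ps <- particle_set(matrix(runif(2 * n, 0, 10), n, 2))
  ps$vel <- with_seed_test(8, matrix(rnorm(2 * n, sd = 1), n, 2))  # kBT = 1
  t0 <- kinetic_temperature(ps, drift_removal = FALSE)
  expect_equal(t0, 1, tolerance = 0.05)

  # uniform drift with drift removal on: same estimate
  ps2 <- ps
  ps2$vel[, 1] <- ps2$vel[, 1] + 5
  expect_equal(kinetic_temperature(ps2, drift_removal = TRUE, W = 10),
               kinetic_temperature(ps, drift_removal = TRUE, W = 10),
               tolerance = 1e-12)

  expect_error(kinetic_temperature(
    particle_set(rbind(c(0, 0)), species = "wall")), "mobile")
})

test_that("forces match brute-force evaluation bit-for-bit via the pair RNG", {
  # same configuration evaluated through the cell list twice gives
  # identical forces (deterministic replay)
  box <- box_spec(12, 9)
  params <- dpd_params(seed = 3)
  ps <- random_fluid(150, 12, 9, seed = 12)
  ps <- thermal_velocities(ps, 1, seed = 13)
  f1 <- dpd_pair_forces(ps, params, box, step = 5)
  f2 <- dpd_pair_forces(ps, params, box, step = 5)
  expect_identical(f1, f2)
})
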