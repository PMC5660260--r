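# VWF / repulsive polymer chain: contour length, bond and LJ forces,
# geometry metrics

test_that("contour length worked examples", {
  expect_equal(contour_length(26, 0.6), 15)
  expect_equal(contour_length(17, 0.6), 9.6)
  expect_equal(contour_length(42, 0.6), 24.6)
  expect_equal(contour_length(2, 0.6), 0.6)
  expect_error(contour_length(1), "2 beads")
  expect_error(chain_params(N = 1), "2 beads")
})

test_that("bond forces: zero at l_b, worked restoring force, -grad U", {
  cp <- chain_params(N = 5)
  built <- build_chain(c(0, 0), cp, conformation = "straight")
  f0 <- bond_forces(built$chain, built$particles)
  expect_lt(max(abs(f0)), 1e-9)

  # one bond stretched by a_m with k_s = 400 kBT/a_m^2: restoring force
  # 400 kBT / a_m on each of its beads
  ps <- built$particles
  ps$pos[5, 1] <- ps$pos[5, 1] + cp$a_m
  f <- bond_forces(built$chain, ps)
  expect_equal(f[5, 1], -400 / cp$a_m, tolerance = 1e-9)
  expect_equal(f[4, 1] - f0[4, 1], 400 / cp$a_m, tolerance = 1e-9)
  expect_equal(f[5, 2], 0)

  tc <- make_test_chain(seed = 31)
  f <- bond_forces(tc$chain, tc$ps, tc$box)
  g <- fd_gradient(chain_energy_fn(tc$chain, tc$box, "bond"), tc$ps$pos,
                   rows = c(1, 9, 26))
  scale <- max(abs(f))
  expect_equal(f[c(1, 9, 26), ] / scale, -g[c(1, 9, 26), ] / scale,
               tolerance = 1e-6)
})

test_that("LJ pair forces: zero crossing, minimum, truncation, -grad U", {
  cp <- chain_params(N = 3)
  sig <- cp$sigma
  mk <- function(r, mode) {
    cpm <- chain_params(N = 3, mode = mode)
    built <- build_chain(c(0, 0), cpm, conformation = "straight")
    ps <- built$particles
    # beads 1..3 along x; move bead 3 to distance r from bead 1
    ps$pos <- rbind(c(0, 0), c(10, 10), c(r, 0))
    list(ps = ps, chain = built$chain)
  }
  # r = sigma: force repulsive (bead 3 pushed to +x)
  s <- mk(sig, "attractive")
  f <- lj_pair_forces(s$chain, s$ps)
  expect_gt(f[3, 1], 0)
  # r = 2^(1/6) sigma: zero force in both modes
  for (mode in c("attractive", "repulsive")) {
    s <- mk(2^(1/6) * sig, mode)
    f <- lj_pair_forces(s$chain, s$ps)
    expect_equal(f[3, 1], 0, tolerance = 1e-9)
  }
  # repulsive at r = 1.5 sigma: exactly zero force and energy
  s <- mk(1.5 * sig, "repulsive")
  f <- lj_pair_forces(s$chain, s$ps)
  expect_identical(f[3, ], c(0, 0))
  ps3 <- s$ps
  en <- chain_energy_fn(s$chain, box_spec(40, 40), "lj")
  expect_identical(en(ps3$pos), 0)

  # attractive mode beyond 2.5 sigma cutoff: zero
  s <- mk(2.6 * sig, "attractive")
  expect_identical(lj_pair_forces(s$chain, s$ps)[3, ], c(0, 0))

  for (mode in c("attractive", "repulsive")) {
    tc <- make_test_chain(seed = 32, mode = mode)
    f <- lj_pair_forces(tc$chain, tc$ps, tc$box)
    g <- fd_gradient(chain_energy_fn(tc$chain, tc$box, "lj"), tc$ps$pos,
                     rows = c(2, 13, 25))
    scale <- max(abs(f))
    expect_equal(f[c(2, 13, 25), ] / scale, -g[c(2, 13, 25), ] / scale,
                 tolerance = 1e-6)
  }
})

test_that("chain extension: straight chain, globule bound, periodic unwrap", {
  cp <- chain_params(N = 26)
  built <- build_chain(c(10, 5), cp, conformation = "straight")
  expect_equal(chain_extension(built$chain, built$particles), 15)

  coil <- build_chain(c(10, 5), cp, conformation = "coil")
  rs <- chain_extension(coil$chain, coil$particles)
  expect_lt(rs, 0.35 * cp$L_VWF)          # compact

  # chain straddling the periodic x boundary: same R_s as translated copy
  box <- box_spec(20, 12)
  ps <- built$particles
  ps$pos[, 1] <- (ps$pos[, 1] + 7) %% 20  # now crosses x = 0
  expect_true(any(diff(ps$pos[, 1]) < 0))
  expect_equal(chain_extension(built$chain, ps, box), 15, tolerance = 1e-10)
})

test_that("radius of gyration: coincident beads, two beads, rod formula", {
  cp2 <- chain_params(N = 2)
  ps <- particle_set(rbind(c(0, 0), c(0, 0) + 1e-30), species = "vwf",
                     struct_id = c(0L, 0L), bead_index = 0:1)
  ch0 <- build_chain(c(0, 0), cp2)$chain
  expect_equal(radius_of_gyration(ch0, ps), 0, tolerance = 1e-15)

  ps2 <- particle_set(rbind(c(0, 0), c(3, 4)), species = "vwf",
                      struct_id = c(0L, 0L), bead_index = 0:1)
  ch2 <- build_chain(c(0, 0), cp2)$chain
  expect_equal(radius_of_gyration(ch2, ps2), 2.5)   # d/2

  # rod of N equally spaced beads: Rg^2 = l^2 (N^2 - 1) / 12
  n <- 26; l <- 0.6
  rod <- build_chain(c(0, 0), chain_params(N = n, l_b = l), "straight")
  expect_equal(radius_of_gyration(rod$chain, rod$particles),
               sqrt(l^2 * (n^2 - 1) / 12), tolerance = 1e-12)
})

test_that("chain and ring forces conserve momentum", {
  tc <- make_test_chain(seed = 33)
  f <- bond_forces(tc$chain, tc$ps, tc$box) +
    lj_pair_forces(tc$chain, tc$ps, tc$box)
  expect_equal(colSums(f), c(0, 0), tolerance = 1e-10)

  tr <- make_test_ring(seed = 34)
  f <- spring_forces(tr$ring, tr$ps, tr$box) +
    bending_forces(tr$ring, tr$ps, tr$box) +
    area_constraint_forces(tr$ring, tr$ps, tr$box)
  expect_equal(colSums(f), c(0, 0), tolerance = 1e-10)
})
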