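# the analysis stack: COM density, RBC-free layer, margination probability,
# regional stretch, bead activity, adhesion potential

make_static_traj <- function(objects, L = 30, W = 20, n_snapshots = 5) {
  generate_fixture(fixture_scene(L, W, n_snapshots, objects))
}

test_that("COM distribution: single bin, uniform, brute-force recount", {
  fx <- make_static_traj(list(fx_straight_chain(center = c(10, 10))))
  d <- com_distribution(fx$trajectory, "vwf", n_bins = 20)
  expect_equal(sum(d$density > 0), 1L)
  expect_equal(sum(d$density) * diff(d$y[1:2]), 1)     # integrates to 1

  # several chains at spread heights: counts equal a direct recount
  ys <- c(2.5, 7.5, 12.5, 17.5, 7.5)
  objs <- lapply(seq_along(ys), function(i)
    fx_straight_chain(N = 6, center = c(4 * i, ys[i])))
  fx <- make_static_traj(objs)
  d <- com_distribution(fx$trajectory, "vwf", n_bins = 4)
  expect_equal(d$count, 5 * c(1, 2, 1, 1))             # 5 snapshots each
  expect_equal(sum(d$density) * diff(d$y[1:2]), 1)

  expect_error(com_distribution(fx$trajectory, "repulsive"), "no structures")
})

test_that("COM density folds symmetrically onto half the channel", {
  objs <- list(fx_straight_chain(N = 6, center = c(5, 3)),
               fx_straight_chain(N = 6, center = c(15, 17)))
  fx <- make_static_traj(objs)
  d <- com_distribution(fx$trajectory, "vwf", n_bins = 10, fold = TRUE)
  expect_equal(sum(d$density > 0), 1L)   # both fold onto y = 3
  expect_equal(d$y[d$density > 0], 3, tolerance = 1)
})

test_that("RBC-free layer: wall-line fixtures, touching wall, no RBCs", {
  fx <- make_static_traj(list(fx_rbc_wall_line("lower", dist = 2)))
  cfl <- rbc_free_layer(fx$trajectory)
  expect_equal(unname(cfl$per_wall["lower"]),
               unname(fx$truth$delta_cfl["lower"]))
  expect_equal(unname(cfl$per_wall["lower"]), 2)
  expect_false(cfl$no_core)

  # both walls at different distances
  fx2 <- make_static_traj(list(fx_rbc_wall_line("lower", dist = 1.5),
                               fx_rbc_wall_line("upper", dist = 2.5)))
  cfl2 <- rbc_free_layer(fx2$trajectory)
  expect_equal(unname(cfl2$per_wall), unname(fx2$truth$delta_cfl))

  # line touching the wall: zero thickness on that side
  fx3 <- make_static_traj(list(fx_rbc_wall_line("lower", dist = 0)))
  expect_equal(unname(rbc_free_layer(fx3$trajectory)$per_wall["lower"]), 0)

  # no RBCs: W/2 with the no-core flag
  fx4 <- make_static_traj(list(fx_straight_chain(center = c(10, 10))))
  cfl4 <- rbc_free_layer(fx4$trajectory)
  expect_true(cfl4$no_core)
  expect_equal(cfl4$delta_cfl, 10)
})

test_that("margination probability: layer membership and uniform oracle", {
  fx <- make_static_traj(list(fx_straight_chain(center = c(10, 1))))
  expect_equal(margination_probability(fx$trajectory, species = "vwf")$P, 1)

  fx2 <- make_static_traj(list(fx_straight_chain(center = c(10, 10))))
  expect_equal(margination_probability(fx2$trajectory, species = "vwf")$P, 0)

  # chains regularly spaced across W = 20 with delta = 2: P = 4/20 exactly
  ys <- seq(0.5, 19.5, by = 1)   # 20 chains, 4 inside the two 2-um layers
  objs <- lapply(seq_along(ys), function(i)
    fx_straight_chain(N = 3, l_b = 0.3, center = c(i * 1.4, ys[i])))
  fx3 <- make_static_traj(objs)
  P <- margination_probability(fx3$trajectory, species = "vwf")
  expect_equal(P$P, 4 / 20)
  expect_equal(P$n_obs, 20L * 5L)
})

test_that("regional stretch: straight chains in both regions, empty-region flag", {
  fx <- make_static_traj(list(
    fx_straight_chain(center = c(7, 1)),        # in the free layer
    fx_straight_chain(center = c(22, 10))))     # in the core
  st <- regional_stretch(fx$trajectory, delta_cfl = 2, species = "vwf")
  expect_equal(st$fl$mean, 1, tolerance = 1e-9)
  expect_equal(st$core$mean, 1, tolerance = 1e-9)
  expect_equal(st$fl$n + st$core$n, 2L * 5L)
  expect_equal(sum(st$fl$hist$density) * diff(st$fl$hist$mid[1:2]), 1,
               tolerance = 1e-9)

  # all chains in the core: FL region flagged empty, not zero-filled
  fx2 <- make_static_traj(list(fx_straight_chain(center = c(10, 10))))
  st2 <- regional_stretch(fx2$trajectory, delta_cfl = 2)
  expect_true(st2$fl$empty)
  expect_true(is.na(st2$fl$mean))

  # mixed fixture: region means match a brute-force recount
  fx3 <- make_static_traj(list(
    fx_straight_chain(N = 11, center = c(5, 1)),
    fx_tight_globule(center = c(15, 1.2)),
    fx_straight_chain(N = 11, center = c(25, 12))))
  st3 <- regional_stretch(fx3$trajectory, delta_cfl = 2, L_VWF = 6)
  truth_rs <- vapply(fx3$truth$chains, `[[`, numeric(1), "R_s")
  in_fl <- vapply(fx3$truth$chains, function(z) z$com[2] <= 2, logical(1))
  expect_equal(st3$fl$mean, mean(pmin(truth_rs[in_fl] / 6, 1.1)),
               tolerance = 1e-9)
  expect_equal(st3$core$mean, mean(pmin(truth_rs[!in_fl] / 6, 1.1)),
               tolerance = 1e-9)
})

test_that("bead activity: straight chain, dense globule, 3-bead 120-degree case", {
  spec <- margination_spec()
  l <- spec$l_b
  straight <- cbind(seq_len(10) * l, 0)
  expect_true(all(bead_activity(straight, spec)))

  # dense cluster, all pairwise distances < R_thres: everyone inactive
  t <- seq(0, 2 * pi, length.out = 9)[-9]
  glob <- 0.35 * spec$R_thres * cbind(cos(t), sin(t))
  expect_false(any(bead_activity(glob, spec)))

  # planar 3-bead chain with 120-degree interior angle at bead 2:
  # middle inactive (120 < 130), ends active (end-end = sqrt(3) l_b > 1.2 l_b)
  xy <- rbind(c(0, 0), c(l, 0),
              c(l + l * cos(pi / 3), l * sin(pi / 3)))
  ang <- acos(sum((xy[1, ] - xy[2, ]) * (xy[3, ] - xy[2, ])) / l^2) * 180 / pi
  expect_equal(ang, 120, tolerance = 1e-9)
  act <- bead_activity(xy, spec)
  expect_identical(act, c(TRUE, FALSE, TRUE))

  # same chain at 140 degrees: middle becomes active
  xy2 <- rbind(c(0, 0), c(l, 0),
               c(l + l * cos(pi * 40 / 180), l * sin(pi * 40 / 180)))
  expect_true(bead_activity(xy2, spec)[2])

  expect_error(bead_activity(rbind(c(0, 0)), spec), "2 beads")
})

test_that("adhesion potential: full layer, empty layer, hand-counted half", {
  # one straight chain lying inside the adhesive layer: Psi = 1
  fx <- make_static_traj(list(fx_straight_chain(center = c(10, 0.5))))
  expect_equal(adhesion_potential(fx$trajectory, species = "vwf")$Psi, 1)
  expect_equal(fx$truth$Psi$vwf, 1)

  # nothing near the wall: Psi = 0
  fx2 <- make_static_traj(list(fx_straight_chain(center = c(10, 10))))
  expect_equal(adhesion_potential(fx2$trajectory, species = "vwf")$Psi, 0)

  # two equal chains: one straight inside the layer, one globule at the
  # centreline: Psi = 1/2 by hand count
  fx3 <- make_static_traj(list(fx_straight_chain(center = c(7, 0.5)),
                               fx_tight_globule(center = c(22, 10))))
  psi <- adhesion_potential(fx3$trajectory, species = "vwf")
  expect_equal(psi$Psi, 0.5)
  expect_equal(fx3$truth$Psi$vwf, 0.5)
  expect_equal(psi$N_tot, 52L)

  # activity can only reduce the in-layer count: Psi <= fraction in layer
  fx4 <- make_static_traj(list(fx_tight_globule(center = c(10, 0.5))))
  psi4 <- adhesion_potential(fx4$trajectory, species = "vwf")
  expect_equal(psi4$Psi, 0)   # in layer but collapsed, hence inactive
})

test_that("margination spec invariants", {
  expect_error(margination_spec(delta = 12, W = 20), "delta")
  expect_error(margination_spec(delta_adhes = 3, delta = 2), "delta")
  expect_error(margination_spec(R_thres = 0.5, l_b = 0.6), "R_thres")
})
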