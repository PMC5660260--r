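# channel assembly: walls, bounce-back, placement, determinism

test_that("wall slabs have the fluid's density and never move", {
  cfg <- channel_config(W = 10, L = 12, H_t = 0, N_VWF = 0L)
  walls <- build_walls(cfg, r_c = 1)
  expect_equal(n_particles(walls), 2L * round(6 * 12 * 1))
  expect_true(all(walls$pos[, 2] < 0 | walls$pos[, 2] > 10))
  expect_true(all(walls$species == vwfmarg:::species_code("wall")))

  # frozen contract: a short driven run leaves wall particles in place
  cfg <- channel_config(W = 6, L = 8, H_t = 0, N_VWF = 0L, g = 0.05,
                        warmup_steps = 0L, sample_steps = 300L, stride = 300L,
                        temp_action = "none")
  traj <- run_channel(cfg)
  wall_idx <- which(traj$species == vwfmarg:::species_code("wall"))
  init_walls <- build_walls(cfg, r_c = 1)
  expect_equal(traj$pos[wall_idx, , n_frames(traj)],
               unname(init_walls$pos), tolerance = 1e-12)
})

test_that("bounce-back mirrors crossers, leaves interior particles, flags blow-up", {
  pos <- rbind(c(1, -0.1), c(1, 0.1), c(1, 20.3))
  vel <- rbind(c(0.5, -1), c(0.5, 1), c(0, 2))
  out <- bounce_back(pos, vel, wall_planes = c(0, 20))
  expect_equal(out$pos[1, 2], 0.1)
  expect_equal(out$vel[1, ], c(-0.5, 1))     # full velocity negation
  expect_equal(out$pos[2, ], c(1, 0.1))      # untouched
  expect_equal(out$vel[2, ], c(0.5, 1))
  expect_equal(out$pos[3, 2], 19.7)
  expect_identical(out$reflected, c(TRUE, FALSE, TRUE))

  expect_error(bounce_back(rbind(c(1, -3)), rbind(c(0, 0)), c(0, 20)),
               "blow-up")
})

test_that("cell count arithmetic and hematocrit realization", {
  rp <- rbc_params()
  # round(H_t W L / A_0_2d) with the default reduced-area target; the box
  # is large enough that integer cell-count quantization stays below the
  # 2% hematocrit tolerance
  cfg <- channel_config(W = 20, L = 100, H_t = 0.3, N_VWF = 0L, kBT = 0.1,
                        relax_steps = 500L)
  pl <- place_cells_and_chains(cfg)
  expect_equal(pl$n_rbc, round(0.3 * 20 * 100 / rp$A_0_2d))
  expect_equal(pl$H_t_realized, 0.3, tolerance = 0.02)
  # placement and relaxation preserve the per-cell target area
  expect_equal(pl$H_t_realized, pl$n_rbc * rp$A_0_2d / (20 * 100),
               tolerance = 0.01)

  # H_t = 0: no cells
  cfg0 <- channel_config(H_t = 0, N_VWF = 0L)
  expect_equal(place_cells_and_chains(cfg0)$n_rbc, 0L)

  expect_error(channel_config(H_t = 0.9), "H_t")
  expect_error(channel_config(W = -1), "dimensions")
})

test_that("placement is deterministic for a fixed seed", {
  cfg <- channel_config(W = 20, L = 40, H_t = 0.2, N_VWF = 4L,
                        chain_mode = "mixed", kBT = 0.1, relax_steps = 300L,
                        seed = 5L)
  p1 <- place_cells_and_chains(cfg)
  p2 <- place_cells_and_chains(cfg)
  expect_identical(p1$particles$pos, p2$particles$pos)
  # chains of both modes present
  sp <- p1$particles$species
  expect_true(any(sp == vwfmarg:::species_code("vwf")))
  expect_true(any(sp == vwfmarg:::species_code("repulsive")))
})

test_that("overcrowding is rejected with a helpful error", {
  cfg <- channel_config(W = 8, L = 12, H_t = 0.75, N_VWF = 0L)
  expect_error(place_cells_and_chains(cfg), "overcrowding|lower H_t")
})

test_that("same config and seed give bit-identical trajectories", {
  cfg <- channel_config(W = 6, L = 8, H_t = 0, N_VWF = 1L, g = 0.02,
                        warmup_steps = 50L, sample_steps = 200L, stride = 50L,
                        seed = 9L, temp_action = "none")
  t1 <- run_channel(cfg)
  t2 <- run_channel(cfg)
  expect_identical(t1$pos, t2$pos)
  expect_identical(t1$vel, t2$vel)

  # manifests identical apart from wall-clock metadata
  m1 <- t1$meta$manifest; m2 <- t2$meta$manifest
  m1$timestamp <- m2$timestamp <- NULL
  expect_identical(m1, m2)
})

test_that("driven pure-fluid flow responds linearly to the body force", {
  base <- list(W = 8, L = 8, H_t = 0, N_VWF = 0L, warmup_steps = 3000L,
               sample_steps = 5000L, stride = 100L, seed = 3L,
               temp_action = "none")
  v1 <- velocity_profile(run_channel(do.call(channel_config,
                                             c(base, g = 0.04))))$vbar
  v2 <- velocity_profile(run_channel(do.call(channel_config,
                                             c(base, g = 0.08))))$vbar
  expect_equal(v2 / v1, 2, tolerance = 0.05)
})

test_that("undriven structure-free fluid stays at rest on average", {
  cfg <- channel_config(W = 8, L = 8, H_t = 0, N_VWF = 0L, g = 0,
                        warmup_steps = 500L, sample_steps = 2000L,
                        stride = 100L, seed = 4L, temp_action = "none")
  fl <- velocity_profile(run_channel(cfg))
  expect_equal(fl$vbar, 0, tolerance = 0.02)
})
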