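test_that("the cylinder bundle reproduces the published configuration", {
  cs <- cylinder_case("full")
  expect_equal(cs$grid$extent, c(32, 2, 1))
  expect_equal(cs$grid$cells[1:2], c(256L, 32L))   # 257 x 33 nodes
  expect_equal(cs$re, 150)
  expect_equal(cs$cfg$nu, 1 / 150)
  expect_true(cs$grid$wall_y && cs$grid$quasi2d)
  # fringe rates: inflow 50 at the domain end, cylinder 100 inside the disc
  expect_equal(max(cs$regions$inflow$lambda$u), 50)
  lam_cyl <- cs$regions$cylinder$lambda$u
  expect_equal(max(lam_cyl), 100)
  on_center <- which.min(abs(cs$grid$xf - 9))
  j_center <- which.min(abs(cs$grid$yc - 1))
  expect_equal(lam_cyl[on_center, j_center, 1], 100)
  far <- which.min(abs(cs$grid$xf - 20))
  expect_equal(lam_cyl[far, j_center, 1], 0)
  # window 1: 4h x h, centered in y, containing the cylinder
  w1 <- cs$windows$w1
  expect_equal(diff(w1$xlim), 4)
  expect_equal(diff(w1$ylim), 1)
  expect_equal(mean(w1$ylim), 1)
  expect_true(w1$xlim[1] < 9 && 9 < w1$xlim[2])
  # windows 2/3 are the left/right halves of window 1
  expect_equal(cs$windows$w2$xlim, c(7, 9))
  expect_equal(cs$windows$w3$xlim, c(9, 11))
  expect_equal(cs$windows$w4$ylim, c(0, 2))
  # reduced bundle scales the grid, not the physics
  cr <- cylinder_case("reduced")
  expect_equal(cr$grid$cells[1:2], c(128L, 16L))
  expect_equal(cr$cfg$nu, cs$cfg$nu)
})

test_that("the channel bundle reproduces the published configuration", {
  ch <- channel_case("reduced")
  expect_equal(ch$grid$extent, c(4 * pi, 2, 2 * pi))
  expect_equal(ch$re, 5000)
  expect_equal(ch$cfg$bulk_u, 0.667)
  expect_false(ch$grid$quasi2d)
  # window 4 covers the whole domain
  w4 <- ch$windows$w4
  expect_equal(w4$xlim, c(0, 4 * pi))
  expect_equal(w4$ylim, c(0, 2))
  # initial condition is the Poiseuille profile (unperturbed)
  f <- ch$ic(ch$grid)
  prof <- apply(f$u, 2, mean)
  expect_equal(prof, ch$grid$yc * (2 - ch$grid$yc), tolerance = 1e-12,
               ignore_attr = TRUE)
  # full-scale grid is 64^3 cells (65^3 nodes)
  expect_equal(channel_case("full")$grid$cells, rep(64L, 3))
  # perturbed variant stays divergence-free
  chp <- channel_case("ci", perturb = 0.03, seed = 3)
  fp <- chp$ic(chp$grid)
  expect_lt(max(abs(divergence(fp, chp$grid))), 1e-10)
  expect_gt(max(abs(fp$v)), 0)
})

test_that("the pulsatile jet phantom has heart-rate timing and refinement", {
  pj <- pulsatile_jet_case()
  expect_equal(pj$T, 60 / 70)
  expect_equal(pj$schedule_exp$n_phi, 22L)
  expect_equal(pj$schedule_num$n_phi, 66L)       # 22 intervals refined x3
  # systolic peak by construction
  tt <- seq(0, pj$T, length.out = 200)
  expect_lt(which.max(pj$waveform(tt)) / 200, 0.5)
  expect_gt(max(pj$waveform(tt)), 0.9)
  # phantom-exterior fringe drives the flow to zero-valued data
  expect_equal(max(pj$regions$walls$lambda$u), 50)
  expect_true(all(pj$regions$walls$lambda$u[pj$mask(
    eval_on(pj$grid, "u", function(x, y, z) x),
    0, eval_on(pj$grid, "u", function(x, y, z) z)) > 0] == 0))
})

test_that("downsampling controls voxel size and validates divisibility", {
  g <- stag_grid(c(8, 8, 2), c(16, 16, 2), wall_y = TRUE)
  w <- list(xlim = c(0, 8), ylim = c(0, 8), zlim = c(0, 2))
  # dw = 0: one node per voxel
  v0 <- window_voxels(g, w, dw = 0)
  m0 <- build_mapping(g, v0)
  expect_true(all(m0$g_v == 1))
  # dw = 1 -> 2x2x2 nodes, dw = 3 -> 4x4x2
  v1 <- window_voxels(g, w, dw = 1)
  expect_equal(unique(build_mapping(g, v1)$g_v), 8L)
  expect_error(window_voxels(g, w, dw = 2), "divisible")
  # membership counts scale as (1+dw)^3
  g3 <- stag_grid(c(8, 8, 4), c(16, 16, 4), wall_y = TRUE)
  v3 <- window_voxels(g3, list(xlim = c(0, 8), ylim = c(0, 8),
                               zlim = c(0, 4)), dw = 3)
  expect_equal(unique(build_mapping(g3, v3)$g_v), 64L)
})

test_that("observations of a steady laminar truth have zero covariance", {
  # steady plug flow imposed by a stability-scaled fringe everywhere
  g <- tiny_wall_grid(8, 8)
  rg <- fringe_region(g, function(x, y, z) rep(1, length(x)),
                      target = c(0.8, 0, 0), stability_scaled = TRUE)
  case <- list(name = "steady", grid = g,
               cfg = solver_config(re = 100, dt = 0.01),
               regions = list(rg),
               ic = function(grid) field_from_fun(grid,
                 fu = function(x, y, z) rep(0.8, length(x))))
  sched <- phase_schedule(0.1, 2)
  vox <- window_voxels(g, list(xlim = c(1, 3), ylim = c(0.5, 1.5),
                               zlim = c(0, 1)), dw = 1)
  ex <- extract_observations(case, vox, sched, pulses = 3)
  expect_lt(max(abs(ex$obs$cov)), 1e-10)
  # mean equals the voxel average of the steady field
  st <- case$ic(g)
  expect_equal(matrix(ex$obs$mean[, , 1], ncol = 3),
               observe(st, ex$mapping, g), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("synthetic channel observations carry a log-law mean profile", {
  cs <- channel_case("ci")
  so <- synthetic_channel_observations(cs, cs$windows$w4, dw = 0,
                                       pulses = 10, seed = 1)
  # bulk of the synthetic mean matches the case's bulk constraint
  expect_equal(mean(so$mean_field[, 1]), 0.667, tolerance = 0.02)
  # covariance is nonzero (turbulent surrogate), zero cross-terms on average
  expect_gt(max(so$obs$cov[, 1, 1]), 0)
  # profile increases monotonically from the wall to the centerline
  g <- cs$grid
  jprof <- so$mean_field[seq(1, by = g$cells[1],
                             length.out = g$cells[2]), 1]
  half <- jprof[seq_len(g$cells[2] / 2)]
  expect_true(all(diff(half) > 0))
})
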