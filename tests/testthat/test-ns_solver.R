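test_that("fringe force is zero outside the region and at the fixed point", {
  g <- tiny_wall_grid()
  rg <- fringe_region(g, function(x, y, z) 50 * (x < 1), target = c(1, 0, 0))
  st <- velocity_field(g)
  Fr <- fringe_force(st, rg, 1, 0.01, g)
  expect_true(all(Fr$u[g$xf >= 1, , ] == 0))
  expect_true(all(Fr$u[g$xf < 1, , ] == 50))   # lambda * (1 - 0)

  # u = U inside the region: zero force everywhere
  st1 <- field_from_fun(g, fu = function(x, y, z) rep(1, length(x)))
  Fr1 <- fringe_force(st1, rg, 1, 0.01, g)
  expect_equal(max(abs(Fr1$u)), 0)

  # lambda identically zero
  rg0 <- fringe_region(g, function(x, y, z) 0 * x)
  Fr0 <- fringe_force(st, rg0, 1, 0.01, g)
  expect_equal(max(abs(Fr0$u)), 0)
  expect_error(fringe_region(g, function(x, y, z) -1 + 0 * x), "negative")
})

test_that("stability-scaled fringe rate equals 1/(alpha dt)", {
  g <- tiny_wall_grid()
  rg <- fringe_region(g, function(x, y, z) 1 * (x < 1), target = c(1, 0, 0),
                      stability_scaled = TRUE)
  st <- velocity_field(g)
  # alpha = 0.5, dt = 0.01 -> lambda = 200 (checked through the force on u=0)
  with_alpha <- function(sub, dt) {
    Fr <- fringe_force(st, rg, sub, dt, g)
    max(Fr$u)
  }
  alpha <- environment(fringe_force)$RK_ALPHA
  dt <- 0.01
  for (k in 1:3)
    expect_equal(with_alpha(k, dt), 1 / (alpha[k] * dt), tolerance = 1e-12)
  # the spec's worked value: alpha 0.5, dt 0.01 -> 200
  expect_equal(1 / (0.5 * 0.01), 200)
})

test_that("stability-scaled fringe drives the flow to the target in a few steps", {
  g <- tiny_wall_grid(8, 8)
  rg <- fringe_region(g, function(x, y, z) 1 * (x < 2), target = c(1, 0, 0),
                      stability_scaled = TRUE)
  cfg <- solver_config(re = 100, dt = 0.01)
  plan <- poisson_plan(g)
  st <- velocity_field(g)
  for (i in 1:5) st <- rk3_step(st, g, cfg, list(rg), cfg$dt, plan)
  inside <- g$xf < 2 - 1e-9
  # within 1% of |U| inside the fringe (projection slightly redistributes)
  expect_lt(max(abs(st$u[inside, , ] - 1)), 0.05)
  expect_lt(mean(abs(st$u[inside, , ] - 1)), 0.01)
})

test_that("Taylor-Green vortex energy decays at the analytic rate", {
  nu <- 0.05
  g <- tiny_periodic_grid(48)
  f <- field_from_fun(g, fu = function(x, y, z) sin(x) * cos(y),
                      fv = function(x, y, z) -cos(x) * sin(y))
  cfg <- solver_config(nu = nu, dt = 0.02)
  ke0 <- kinetic_energy(f, g)
  t_end <- 2
  f2 <- advance_to(f, t_end, g, cfg)
  expect_equal(kinetic_energy(f2, g) / ke0, exp(-4 * nu * t_end),
               tolerance = 0.01)
  expect_lt(max(abs(divergence(f2, g))), 1e-10)
})

test_that("zero field with zero forcing stays exactly zero", {
  g <- tiny_wall_grid()
  cfg <- solver_config(re = 100, dt = 0.01)
  st <- advance_to(velocity_field(g), 0.1, g, cfg)
  expect_equal(max(abs(st$u)), 0)
  expect_equal(max(abs(st$v)), 0)
})

test_that("laminar channel converges to the Poiseuille profile", {
  g <- stag_grid(c(4, 2, 1), c(8, 32, 1), wall_y = TRUE)
  cfg <- solver_config(re = 100, dt = 0.005, bulk_u = 2 / 3)
  st <- advance_to(velocity_field(g), 40, g, cfg)
  prof <- apply(st$u, 2, mean)
  exact <- g$yc * (2 - g$yc)          # max 1, bulk 2/3
  expect_lt(max(abs(prof - exact)) / max(exact), 0.005)
})

test_that("advance_to has the semigroup property and is identity at t", {
  g <- tiny_periodic_grid(16)
  f <- field_from_fun(g, fu = function(x, y, z) sin(x) * cos(y),
                      fv = function(x, y, z) -cos(x) * sin(y))
  cfg <- solver_config(nu = 0.05, dt = 0.01)
  fid <- advance_to(f, f$t, g, cfg)
  expect_identical(fid$u, f$u)
  f1 <- advance_to(f, 0.1, g, cfg)
  f1 <- advance_to(f1, 0.25, g, cfg)
  f2 <- advance_to(f, 0.25, g, cfg)
  expect_equal(f1$u, f2$u, tolerance = 1e-12)
  expect_error(advance_to(f2, 0.1, g, cfg), "past")
})

test_that("projection is idempotent and conserves periodic momentum", {
  set.seed(3)
  g <- tiny_periodic_grid(16)
  plan <- poisson_plan(g)
  f <- velocity_field(g)
  f$u[] <- rnorm(length(f$u)); f$v[] <- rnorm(length(f$v))
  f1 <- project(f, g, plan, 1)
  expect_lt(max(abs(divergence(f1, g))), 1e-11)
  f2 <- project(f1, g, plan, 1)
  expect_lt(max(abs(f2$u - f1$u)), 1e-11)
  # momentum conservation over steps with no forcing
  cfg <- solver_config(nu = 0.01, dt = 0.01)
  mu0 <- mean(f1$u); mv0 <- mean(f1$v)
  f3 <- advance_to(f1, 0.1, g, cfg)
  expect_lt(abs(mean(f3$u) - mu0), 1e-10)
  expect_lt(abs(mean(f3$v) - mv0), 1e-10)
})

test_that("Taylor-Green error converges at second order in spacing", {
  nu <- 0.02; t_end <- 0.5
  err <- vapply(c(12, 24, 48), function(n) {
    g <- stag_grid(c(2 * pi, 2 * pi, 1), c(n, n, 1), wall_y = FALSE)
    f <- field_from_fun(g, fu = function(x, y, z) sin(x) * cos(y),
                        fv = function(x, y, z) -cos(x) * sin(y))
    cfg <- solver_config(nu = nu, dt = 0.005)
    f2 <- advance_to(f, t_end, g, cfg)
    ex <- field_from_fun(g, fu = function(x, y, z)
      sin(x) * cos(y) * exp(-2 * nu * t_end))
    sqrt(mean((f2$u - ex$u)^2))
  }, numeric(1))
  slope <- -coef(lm(log(err) ~ log(c(12, 24, 48))))[2]
  expect_gt(slope, 1.8)
})

test_that("no-slip wall handling rejects periodic axes and pins wall faces", {
  gp <- tiny_periodic_grid(8)
  f <- velocity_field(gp)
  expect_error(no_slip_walls(f, gp), "periodic")
  g <- tiny_wall_grid()
  f <- velocity_field(g)
  f$v[] <- 1
  f <- no_slip_walls(f, g)
  expect_equal(max(abs(f$v[, c(1, dim(f$v)[2]), ])), 0)
})

test_that("3D solver advances a wall-bounded field stably", {
  g <- stag_grid(c(2, 2, 2), c(8, 8, 8), wall_y = TRUE)
  cfg <- solver_config(re = 200, dt = 0.01, bulk_u = 0.5)
  st <- field_from_fun(g, fu = function(x, y, z) y * (2 - y))
  st <- advance_to(st, 0.5, g, cfg)
  expect_true(all(is.finite(st$u)))
  expect_lt(max(abs(divergence(st, g))), 1e-10)
  expect_equal(mean(st$u), 0.5, tolerance = 1e-12)
})
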