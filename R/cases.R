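# Twin-experiment factories: the confined-cylinder and turbulent-channel
# configurations, a synthetic pulsatile-jet phantom, ground-truth runs,
# and voxel observation extraction with windows and downsampling.

#' Confined-cylinder case (periodic vortex shedding, quasi-2D)
#'
#' Channel of size `32h x 2h` (quasi-2D span `h`), cylinder of diameter `h`
#' centered at `(9h, h)`, `Re = 150` based on `h` and the unit plug inflow.
#' The inflow is imposed by a fringe region at the end of the domain
#' (`lambda = 50`, `U = (1, 0, 0)`); the cylinder is an immersed fringe
#' region with `U = 0` and `lambda = 100`; no-slip walls top and bottom.
#' The default grid has 257 x 33 nodes (256 x 32 cells); the reduced scale
#' (129 x 17 nodes) runs the full twin loop at desk scale.
#'
#' @param scale `"full"` (256 x 32 cells) or `"reduced"` (128 x 16).
#' @param with_cylinder include the cylinder fringe region (the DA
#'   prediction runs drop it: only the data reconstruct the wake).
#' @param dt fixed solver time step (defaults per scale).
#' @return case bundle: list with `grid`, `cfg`, `regions`, `ic`,
#'   `windows`, `probe`, `name`, `h`.
#' @export
cylinder_case <- function(scale = c("full", "reduced"),
                          with_cylinder = TRUE, dt = NULL) {
  scale <- match.arg(scale)
  cells <- if (scale == "full") c(256L, 32L, 1L) else c(128L, 16L, 1L)
  if (is.null(dt)) dt <- if (scale == "full") 0.01 else 0.015
  h <- 1
  grid <- stag_grid(c(32, 2, 1) * h, cells, wall_y = TRUE)
  cfg <- solver_config(re = 150, u_ref = 1, l_ref = h, dt = dt)
  inflow <- fringe_region(grid,
    lambda_fun = function(x, y, z) 50 * (x >= 30 * h),
    target = c(1, 0, 0))
  regions <- list(inflow = inflow)
  if (with_cylinder)
    regions$cylinder <- fringe_region(grid,
      lambda_fun = function(x, y, z)
        100 * ((x - 9 * h)^2 + (y - h)^2 <= (h / 2)^2),
      target = c(0, 0, 0))
  ic <- function(grid) {
    # plug flow plus a small deterministic asymmetric pulse near the
    # cylinder so the shedding instability saturates quickly
    field_from_fun(grid,
      fu = function(x, y, z) rep(1, length(x)),
      fv = function(x, y, z)
        0.1 * exp(-((x - 10.5)^2 + (y - 1.3)^2) / 0.5))
  }
  win <- function(xl, yl) list(xlim = xl, ylim = yl, zlim = c(0, h))
  windows <- list(
    w1 = win(c(7, 11) * h, c(0.5, 1.5) * h),
    w2 = win(c(7, 9) * h, c(0.5, 1.5) * h),
    w3 = win(c(9, 11) * h, c(0.5, 1.5) * h),
    w4 = win(c(7, 11) * h, c(0, 2) * h),
    w5 = win(c(7, 9) * h, c(0, 2) * h),
    w6 = win(c(9, 11) * h, c(0, 2) * h),
    full = win(c(0, 32) * h, c(0, 2) * h))
  list(name = paste0("cylinder-", scale), grid = grid, cfg = cfg,
       regions = regions, ic = ic, windows = windows,
       probe = c(15 * h, h, grid$zc[1]), h = h, re = 150,
       D_default = 1000)
}

#' Turbulent-channel case (statistically steady)
#'
#' Channel `4 pi h x 2h x 2 pi h`, periodic in x and z, no-slip y walls,
#' `Re = 5000` based on the half-width `h` and the initial Poiseuille
#' center velocity, constant bulk velocity 0.667 enforced stream-wise.
#' The initial condition is the laminar Poiseuille profile, optionally
#' perturbed with seeded random solenoidal noise to trigger transition in
#' ground-truth runs (unperturbed DA runs rely on the filter to force
#' turbulence).
#'
#' @param scale `"full"` (64^3 cells; 65^3 nodes), `"reduced"` (32^3) or
#'   `"ci"` (24 x 32 x 12, for fast property runs).
#' @param perturb amplitude of the solenoidal perturbation relative to the
#'   center velocity (0 for the unperturbed laminar start).
#' @param seed seed of the perturbation stream.
#' @return case bundle (same shape as [cylinder_case()]).
#' @export
channel_case <- function(scale = c("full", "reduced", "ci"),
                         perturb = 0, seed = 1L) {
  scale <- match.arg(scale)
  cells <- switch(scale, full = c(64L, 64L, 64L),
                  reduced = c(32L, 32L, 32L), ci = c(24L, 32L, 12L))
  h <- 1
  grid <- stag_grid(c(4 * pi, 2, 2 * pi) * h, cells, wall_y = TRUE)
  cfg <- solver_config(re = 5000, u_ref = 1, l_ref = h, dt = NA, cfl = 0.5,
                       bulk_u = 0.667)
  ic <- function(grid) {
    f <- field_from_fun(grid,
      fu = function(x, y, z) y * (2 * h - y) / h^2)
    if (perturb > 0) f <- add_solenoidal_noise(f, grid, perturb, seed)
    f
  }
  win <- function(xl, yl) list(xlim = xl, ylim = yl, zlim = c(0, 2 * pi * h))
  x0 <- 2 * pi * h
  windows <- list(
    w1 = win(c(x0 - pi / 4, x0 + pi / 4) * h, c(0.5, 1.5) * h),
    w2 = win(c(x0 - pi / 4, x0 + pi / 4) * h, c(0, 2) * h),
    w3 = win(c(0, 4 * pi) * h, c(0.5, 1.5) * h),
    w4 = win(c(0, 4 * pi) * h, c(0, 2) * h))
  list(name = paste0("channel-", scale), grid = grid, cfg = cfg,
       regions = list(), ic = ic, windows = windows,
       probe = c(2 * pi * h, h, pi * h), h = h, re = 5000,
       D_default = 10)
}

# Seeded random divergence-free perturbation (projection of white noise),
# replacing deterministic Tollmien-Schlichting seeding.
add_solenoidal_noise <- function(field, grid, amplitude, seed) {
  set.seed(seed)
  noise <- velocity_field(grid)
  noise$u[] <- stats::rnorm(length(noise$u))
  nyv <- dim(noise$v)[2]
  if (grid$wall_y) {
    noise$v[, 2:(nyv - 1), ] <- stats::rnorm(length(noise$v[, 2:(nyv - 1), ]))
  } else noise$v[] <- stats::rnorm(length(noise$v))
  if (!grid$quasi2d) noise$w[] <- stats::rnorm(length(noise$w))
  plan <- poisson_plan(grid)
  noise <- project(noise, grid, plan, 1)
  sc <- amplitude / max(abs(noise$u))
  field$u <- field$u + sc * noise$u
  field$v <- field$v + sc * noise$v
  if (!grid$quasi2d) field$w <- field$w + sc * noise$w
  field$p[] <- 0
  field
}

#' Synthetic pulsatile-jet phantom case
#'
#' A round pulsatile jet inside a cylindrical phantom on a Cartesian grid,
#' emulating the structure of a measured valve-flow pipeline: walls are
#' imposed through a fringe region built from zero-valued data outside the
#' phantom, the inflow through the lowest y-slices with a time-interpolated
#' pulsatile target, and the bulk region is left to data assimilation.
#' The pulse period is `T = 60/70` s (heart rate 70 beats/min); the
#' measurement phase schedule (22 intervals) is refined by a factor 3 to 66
#' for the numerical runs.
#'
#' @param cells grid cells (default `c(16, 24, 16)`).
#' @param peak_velocity systolic peak inflow velocity.
#' @return case bundle; also carries `schedule_exp` (22 phases) and
#'   `schedule_num` (66 phases) plus the phantom `mask` function.
#' @export
pulsatile_jet_case <- function(cells = c(16L, 24L, 16L),
                               peak_velocity = 1) {
  T <- 60 / 70
  Lx <- 2; Ly <- 3; Lz <- 2
  grid <- stag_grid(c(Lx, Ly, Lz), cells, wall_y = FALSE)
  cfg <- solver_config(re = 500, u_ref = peak_velocity, l_ref = 1,
                       dt = NA, cfl = 0.4)
  R <- 0.8                               # phantom radius
  r2 <- function(x, z) (x - Lx / 2)^2 + (z - Lz / 2)^2
  mask <- function(x, y, z) r2(x, z) <= R^2
  waveform <- function(t) {
    ph <- (t %% T) / T
    peak_velocity * (0.15 + pmax(sin(pi * ph / 0.4), 0)^2 * (ph < 0.4))
  }
  jet_r <- 0.35
  inflow_target <- function(t, grid) {
    amp <- waveform(t)
    prof <- eval_on(grid, "v", function(x, y, z)
      amp * exp(-r2(x, z) / jet_r^2))
    list(u = 0, v = prof, w = 0)
  }
  walls <- fringe_region(grid,
    lambda_fun = function(x, y, z) 50 * (r2(x, z) > R^2),
    target = c(0, 0, 0))
  inflow <- fringe_region(grid,
    lambda_fun = function(x, y, z)
      50 * (y < 5 * Ly / cells[2]) * (r2(x, z) <= R^2),
    target = inflow_target, stability_scaled = FALSE)
  ic <- function(grid) velocity_field(grid)
  sched_exp <- phase_schedule(T, 22L)
  sched_num <- refine_schedule(sched_exp, 3L)
  windows <- list(bulk = list(xlim = c(0, Lx),
                              ylim = c(5 * Ly / cells[2], Ly),
                              zlim = c(0, Lz)))
  list(name = "pulsatile-jet", grid = grid, cfg = cfg,
       regions = list(walls = walls, inflow = inflow), ic = ic,
       windows = windows, probe = c(Lx / 2, Ly / 2, Lz / 2),
       schedule_exp = sched_exp, schedule_num = sched_num,
       mask = mask, waveform = waveform, T = T, D_default = 10)
}

#' Refine a phase schedule by an integer factor
#'
#' Splits every inter-phase interval (including the wrap-around interval
#' through `T`) into `factor` equal parts: 22 intervals become 66 with
#' `factor = 3`.
#'
#' @param schedule a [phase_schedule()].
#' @param factor integer refinement factor.
#' @return the refined [phase_schedule()].
#' @export
refine_schedule <- function(schedule, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1L)
  tp <- schedule$t_phi
  bounds <- c(0, tp)
  t_new <- unlist(lapply(seq_len(length(bounds) - 1L), function(i)
    bounds[i] + diff(bounds)[i] * seq_len(factor) / factor))
  phase_schedule(schedule$T, schedule$n_phi * factor, t_phi = t_new)
}

#' Voxel lattice covering a window at downsampling factor `dw`
#'
#' Voxels comprise `(1 + dw)^3` adjacent grid nodes: the voxel edge is
#' `(1 + dw)` cells and the window extent must be divisible by it on every
#' resolved axis.
#'
#' @param grid the [stag_grid()].
#' @param window list with `xlim`, `ylim`, `zlim` (aligned to cell faces).
#' @param dw integer downsampling factor `>= 0`.
#' @return a [voxel_grid()].
#' @export
window_voxels <- function(grid, window, dw = 1L) {
  dw <- as.integer(dw)
  stopifnot(dw >= 0L)
  lims <- rbind(window$xlim, window$ylim, window$zlim)
  lo <- round((lims[, 1] - grid$origin) / grid$spacing)
  hi <- round((lims[, 2] - grid$origin) / grid$spacing)
  ncell <- hi - lo
  k <- dw + 1L
  nvox <- ncell / k
  if (grid$quasi2d) nvox[3] <- max(nvox[3], 1)
  if (any(abs(nvox - round(nvox)) > 1e-9))
    stop(sprintf("window of %s cells not divisible by voxel size %d",
                 paste(ncell, collapse = "x"), k))
  nvox <- pmax(as.integer(round(nvox)), 1L)
  h <- k * grid$spacing
  if (grid$quasi2d) h[3] <- grid$spacing[3]
  voxel_grid(origin = grid$origin + lo * grid$spacing, h = h,
             counts = nvox, dw = dw)
}

#' Run the forward model without filtering
#'
#' @param case a case bundle.
#' @param t_end end time.
#' @param state optional initial state (defaults to the case's `ic`).
#' @param each_step optional per-step callback.
#' @return the final `velocity_field`.
#' @export
run_dns <- function(case, t_end, state = NULL, each_step = NULL) {
  if (is.null(state)) state <- case$ic(case$grid)
  plan <- poisson_plan(case$grid)
  advance_to(state, t_end, case$grid, case$cfg, case$regions, plan,
             each_step = each_step)
}

#' Measure the vortex-shedding period of a case
#'
#' Runs the forward model past the spin-up, records the cross-stream
#' velocity at the wake probe every step for `record_time`, and estimates
#' the period by spectral peak interpolation ([estimate_period()]).
#'
#' @param case a case bundle with a fixed `dt` and a `probe` location.
#' @param spin_up transient time discarded before recording.
#' @param record_time length of the recorded signal (should span at least
#'   20 shedding cycles).
#' @param state optional pre-spun state (skips the spin-up).
#' @return list with `period`, the probe `signal` and the sampling `dt`.
#' @export
shedding_period <- function(case, spin_up = 60, record_time = 60,
                            state = NULL) {
  grid <- case$grid; dt <- case$cfg$dt
  stopifnot(!is.na(dt))
  i <- which.min(abs(grid$xc - case$probe[1]))
  j <- which.min(abs(grid$yf - case$probe[2]))
  if (is.null(state)) state <- run_dns(case, spin_up)
  n_rec <- ceiling(record_time / dt)
  sig <- numeric(n_rec); idx <- 0L
  rec <- function(st) {
    idx <<- idx + 1L
    if (idx <= n_rec) sig[idx] <<- st$v[i, j, 1]
  }
  state <- run_dns(case, state$t + n_rec * dt, state = state,
                   each_step = rec)
  list(period = estimate_period(sig[seq_len(min(idx, n_rec))], dt),
       signal = sig, dt = dt, state = state)
}

#' Extract voxel observations from a ground-truth run (twin experiment)
#'
#' Integrates the ground-truth configuration past `spin_up`, then for each
#' of `pulses` pulses records the voxel average of the center-interpolated
#' solution at every phase time, and finally phase-averages the per-pulse
#' samples into mean and covariance (biased, divisor `p`).  The
#' ground-truth phase means are accumulated alongside for twin-experiment
#' error measures.
#'
#' @param case the ground-truth case bundle.
#' @param voxels a [voxel_grid()] (see [window_voxels()]).
#' @param schedule the [phase_schedule()].
#' @param pulses number of recorded pulses `p`.
#' @param spin_up transient time discarded before recording.
#' @param state optional pre-spun state.
#' @param keep_samples retain per-pulse samples in the observation set.
#' @return list with `obs` (an [observation_set()]), `truth`
#'   (a [running_moments()] of the ground truth, `D = 0`), `mapping` and
#'   the final `state`.
#' @export
extract_observations <- function(case, voxels, schedule, pulses,
                                 spin_up = 0, state = NULL,
                                 keep_samples = TRUE) {
  stopifnot(pulses >= 1)
  grid <- case$grid
  mapping <- build_mapping(grid, voxels)
  plan <- poisson_plan(grid)
  if (is.null(state)) state <- case$ic(grid)
  if (spin_up > state$t)
    state <- advance_to(state, spin_up, grid, case$cfg, case$regions, plan)
  t0 <- state$t
  n_phi <- schedule$n_phi
  samples <- lapply(seq_len(n_phi), function(phi)
    array(0, c(pulses, mapping$m_v, 3)))
  truth <- running_moments(n_cells(grid), n_phi, D = 0)
  for (s in seq_len(pulses)) {
    for (phi in seq_len(n_phi)) {
      t_n <- t0 + phase_time(schedule, s, phi)
      state <- advance_to(state, t_n, grid, case$cfg, case$regions, plan)
      Xc <- interpolate_to_centers(state, grid)
      samples[[phi]][s, , ] <- observe(Xc, mapping)
      truth <- update_moments(truth, Xc, phi)
    }
  }
  obs <- phase_average_samples(samples, schedule, voxels,
                               keep_samples = keep_samples)
  list(obs = obs, truth = truth, mapping = mapping, state = state)
}

#' Synthetic statistically-steady channel observations
#'
#' Builds an observation set for the channel window from a prescribed
#' turbulent mean profile (Reichardt's law-of-the-wall closure, which
#' blends the viscous sublayer into the logarithmic region) plus seeded
#' Gaussian fluctuation samples with a near-wall-peaked rms shape.  This is
#' a synthetic stand-in for paper-scale ground-truth statistics: it gives
#' desk-scale runs observations with a realistic log-law mean and
#' non-trivial covariance without the long turbulence-resolving
#' integration.
#'
#' @param case a [channel_case()] bundle.
#' @param window one of the case windows.
#' @param dw downsampling factor.
#' @param pulses number of synthetic pulses `p`.
#' @param u_tau friction velocity of the synthetic profile; `NULL` solves
#'   it so the bulk velocity matches the case's bulk constraint.
#' @param intensity fluctuation rms in units of `u_tau`.
#' @param seed seed of the fluctuation stream.
#' @return list with `obs`, `mapping`, the center mean field `mean_field`
#'   (`n x 3`) and `u_tau`.
#' @export
synthetic_channel_observations <- function(case, window, dw = 0L,
                                           pulses = 50L, u_tau = NULL,
                                           intensity = 2, seed = 1L) {
  grid <- case$grid
  nu <- case$cfg$nu
  h <- case$h
  reichardt <- function(yp) {
    k <- 0.41
    (1 / k) * log(1 + k * yp) +
      7.8 * (1 - exp(-yp / 11) - (yp / 11) * exp(-yp / 3))
  }
  ubulk_of <- function(ut) {
    yy <- seq(0, h, length.out = 513)[-1]
    ut * mean(reichardt(pmin(yy, 2 * h - yy) * ut / nu))
  }
  if (is.null(u_tau)) {
    target <- if (is.na(case$cfg$bulk_u)) 0.667 else case$cfg$bulk_u
    u_tau <- stats::uniroot(function(ut) ubulk_of(ut) - target,
                            c(1e-4, 0.2))$root
  }
  ydist <- pmin(grid$yc, 2 * h - grid$yc)
  u_mean_y <- u_tau * reichardt(ydist * u_tau / nu)
  yp <- ydist * u_tau / nu
  rms_y <- intensity * u_tau * (yp / 15) * exp(1 - yp / 15)
  cells <- grid$cells
  jcol <- rep(rep(seq_len(cells[2]), each = cells[1]), cells[3])
  mean_field <- cbind(u_mean_y[jcol], 0, 0)
  voxels <- window_voxels(grid, window, dw)
  mapping <- build_mapping(grid, voxels)
  set.seed(seed)
  sched <- phase_schedule(1, 1L, dtau = 1)
  samples <- list(array(0, c(pulses, mapping$m_v, 3)))
  n <- nrow(mean_field)
  for (s in seq_len(pulses)) {
    fluct <- cbind(rms_y[jcol] * stats::rnorm(n),
                   0.6 * rms_y[jcol] * stats::rnorm(n),
                   0.8 * rms_y[jcol] * stats::rnorm(n))
    samples[[1]][s, , ] <- observe(mean_field + fluct, mapping)
  }
  obs <- phase_average_samples(samples, sched, voxels, keep_samples = TRUE)
  list(obs = obs, mapping = mapping, mean_field = mean_field,
       u_tau = u_tau)
}
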