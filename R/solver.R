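# Incompressible Navier-Stokes forward model: second-order central
# differences on the MAC grid, explicit low-storage three-stage Runge-Kutta
# with a pressure projection per stage, and volumetric fringe forcing for
# inflow, immersed objects and data-driven walls.

RK_GAMMA <- c(8 / 15, 5 / 12, 3 / 4)
RK_ZETA  <- c(0, -17 / 60, -5 / 12)
RK_ALPHA <- RK_GAMMA + RK_ZETA            # effective stage advancement

#' Solver configuration
#'
#' @param nu kinematic viscosity (length^2/time).  Give either `nu` or
#'   `re` with the reference scales.
#' @param re Reynolds number `u_ref * l_ref / nu`.
#' @param u_ref,l_ref reference velocity and length.
#' @param dt fixed time step; `NA` to derive from `cfl` each step.
#' @param cfl advective CFL number used when `dt` is `NA`.
#' @param rho fluid density.
#' @param bulk_u target volume-averaged stream-wise velocity (`NA` for
#'   none); enforced after each stage by a uniform body force.
#' @param div_tol tolerance on the post-projection divergence.
#' @return object of class `solver_config`.
#' @export
solver_config <- function(nu = NULL, re = NULL, u_ref = 1, l_ref = 1,
                          dt = NA, cfl = 0.4, rho = 1, bulk_u = NA,
                          div_tol = 1e-8) {
  if (is.null(nu)) {
    if (is.null(re)) stop("give either nu or re")
    nu <- u_ref * l_ref / re
  }
  if (is.null(re)) re <- u_ref * l_ref / nu
  stopifnot(nu > 0, is.na(dt) || dt > 0)
  structure(list(nu = nu, re = re, u_ref = u_ref, l_ref = l_ref,
                 dt = dt, cfl = cfl, rho = rho, bulk_u = bulk_u,
                 div_tol = div_tol,
                 rk = list(gamma = RK_GAMMA, zeta = RK_ZETA,
                           alpha = RK_ALPHA)),
            class = "solver_config")
}

#' Fringe (penalty) region
#'
#' A volumetric force `f = lambda (U - u)` active where `lambda > 0`,
#' driving the flow toward a target velocity `U(x, t)`; used for inflow,
#' immersed objects (`U = 0`) and data-derived walls.
#'
#' @param grid a [stag_grid()].
#' @param lambda_fun vectorized `function(x, y, z)` returning the fringe
#'   rate (1/time), zero outside the region; evaluated at every face
#'   location of each component.
#' @param target either a length-3 numeric (constant `U`) or a
#'   `function(t, grid)` returning a list `u`, `v`, `w` of face arrays
#'   (time-interpolated voxel slices, profiles, ...).
#' @param stability_scaled if `TRUE` the rate is replaced inside the
#'   region by `1/(alpha_k dt)` at Runge-Kutta stage `k`, the largest rate
#'   the explicit scheme tolerates (which drives `u` to `U` in one stage).
#' @return object of class `fringe_region`.
#' @export
fringe_region <- function(grid, lambda_fun, target = c(0, 0, 0),
                          stability_scaled = FALSE) {
  lam <- list(u = eval_on(grid, "u", lambda_fun),
              v = eval_on(grid, "v", lambda_fun),
              w = eval_on(grid, "w", lambda_fun))
  if (any(lam$u < 0, lam$v < 0, lam$w < 0))
    stop("negative fringe rate lambda")
  if (!is.function(target)) {
    tval <- as.numeric(target)
    stopifnot(length(tval) == 3L)
    target <- local({
      const <- tval
      function(t, grid) list(u = const[1], v = const[2], w = const[3])
    })
  }
  structure(list(lambda = lam, target = target,
                 stability_scaled = stability_scaled),
            class = "fringe_region")
}

#' Fringe force of one region
#'
#' Returns `lambda * (U - u)` on each face family.  With the
#' stability-scaled flag set, `lambda = 1/(alpha(substep) * dt)` inside the
#' region (`alpha` being the effective advancement fraction of the stage).
#'
#' @param state a `velocity_field`.
#' @param region a [fringe_region()].
#' @param substep Runge-Kutta stage index (1..3).
#' @param dt full time step.
#' @param grid the grid.
#' @return list of face arrays `u`, `v`, `w`.
#' @export
fringe_force <- function(state, region, substep, dt, grid) {
  U <- region$target(state$t, grid)
  lam <- region$lambda
  if (region$stability_scaled) {
    rate <- 1 / (RK_ALPHA[substep] * dt)
    lam <- list(u = rate * (lam$u > 0), v = rate * (lam$v > 0),
                w = rate * (lam$w > 0))
  }
  list(u = lam$u * (U$u - state$u),
       v = lam$v * (U$v - state$v),
       w = lam$w * (U$w - state$w))
}

# Advective + diffusive right-hand side per component (conservative form,
# 2nd-order central).  Returns a list of face arrays; v boundary rows are
# zero on wall grids.
momentum_rhs <- function(state, grid, nu) {
  nx <- grid$cells[1]; ny <- grid$cells[2]; nz <- grid$cells[3]
  h <- grid$spacing
  u <- state$u; v <- state$v; w <- state$w
  wall <- grid$wall_y
  ixp <- grid$ixp; ixm <- grid$ixm; izp <- grid$izp; izm <- grid$izm

  ue <- pad_y(u, grid)                               # (nx, ny+2, nz)
  # u and v averaged to the xy cell corners (x-face / y-face intersections)
  if (wall) {
    ub <- 0.5 * (ue[, 1:(ny + 1L), , drop = FALSE] +
                 ue[, 2:(ny + 2L), , drop = FALSE])  # (nx, ny+1, nz)
  } else {
    ub <- 0.5 * (u[, grid$iym, , drop = FALSE] + u)  # (nx, ny, nz)
  }
  vb <- 0.5 * (v[ixm, , , drop = FALSE] + v)         # same shape as v

  ## ---- u momentum ----------------------------------------------------
  uc <- 0.5 * (u + u[ixp, , , drop = FALSE])         # u at centers
  Fx <- uc * uc
  adv <- (Fx - Fx[ixm, , , drop = FALSE]) / h[1]
  Fy <- ub * vb
  if (wall) {
    adv <- adv + (Fy[, 2:(ny + 1L), , drop = FALSE] -
                  Fy[, 1:ny, , drop = FALSE]) / h[2]
  } else {
    adv <- adv + (Fy[, grid$iyp, , drop = FALSE] - Fy) / h[2]
  }
  lap <- (u[ixp, , , drop = FALSE] - 2 * u + u[ixm, , , drop = FALSE]) / h[1]^2 +
         (ue[, 3:(ny + 2L), , drop = FALSE] - 2 * u +
          ue[, 1:ny, , drop = FALSE]) / h[2]^2
  if (nz > 1L) {
    uz <- 0.5 * (u[, , izm, drop = FALSE] + u)       # u at z-faces
    wbx <- 0.5 * (w[ixm, , , drop = FALSE] + w)      # w at x-face/z-face
    Fz <- uz * wbx
    adv <- adv + (Fz[, , izp, drop = FALSE] - Fz) / h[3]
    lap <- lap + (u[, , izp, drop = FALSE] - 2 * u +
                  u[, , izm, drop = FALSE]) / h[3]^2
  }
  Hu <- -adv + nu * lap

  ## ---- v momentum ----------------------------------------------------
  G <- ub * vb
  advv <- (G[ixp, , , drop = FALSE] - G) / h[1]
  if (wall) {
    vc <- 0.5 * (v[, 1:ny, , drop = FALSE] + v[, 2:(ny + 1L), , drop = FALSE])
    Fy <- vc * vc                                    # (nx, ny, nz), centers
    advv[, 2:ny, ] <- advv[, 2:ny, , drop = FALSE] +
      (Fy[, 2:ny, , drop = FALSE] - Fy[, 1:(ny - 1L), , drop = FALSE]) / h[2]
    lapv <- array(0, dim(v))
    lapv[, 2:ny, ] <-
      (v[ixp, 2:ny, , drop = FALSE] - 2 * v[, 2:ny, , drop = FALSE] +
       v[ixm, 2:ny, , drop = FALSE]) / h[1]^2 +
      (v[, 3:(ny + 1L), , drop = FALSE] - 2 * v[, 2:ny, , drop = FALSE] +
       v[, 1:(ny - 1L), , drop = FALSE]) / h[2]^2
  } else {
    vc <- 0.5 * (v + v[, grid$iyp, , drop = FALSE])
    Fy <- vc * vc
    advv <- advv + (Fy - Fy[, grid$iym, , drop = FALSE]) / h[2]
    lapv <- (v[ixp, , , drop = FALSE] - 2 * v + v[ixm, , , drop = FALSE]) / h[1]^2 +
            (v[, grid$iyp, , drop = FALSE] - 2 * v +
             v[, grid$iym, , drop = FALSE]) / h[2]^2
  }
  if (nz > 1L) {
    vz <- 0.5 * (v[, , izm, drop = FALSE] + v)       # v at z-faces
    we <- pad_y(w, grid)
    if (wall) {
      wby <- 0.5 * (we[, 1:(ny + 1L), , drop = FALSE] +
                    we[, 2:(ny + 2L), , drop = FALSE])   # w at y-faces
    } else {
      wby <- 0.5 * (w[, grid$iym, , drop = FALSE] + w)
    }
    Fz <- vz * wby
    dFz <- (Fz[, , izp, drop = FALSE] - Fz) / h[3]
    d2z <- (v[, , izp, drop = FALSE] - 2 * v + v[, , izm, drop = FALSE]) / h[3]^2
    if (wall) {
      advv[, 2:ny, ] <- advv[, 2:ny, , drop = FALSE] + dFz[, 2:ny, , drop = FALSE]
      lapv[, 2:ny, ] <- lapv[, 2:ny, , drop = FALSE] + d2z[, 2:ny, , drop = FALSE]
    } else {
      advv <- advv + dFz
      lapv <- lapv + d2z
    }
  }
  Hv <- -advv + nu * lapv
  if (wall) { Hv[, 1L, ] <- 0; Hv[, dim(v)[2], ] <- 0 }

  ## ---- w momentum ----------------------------------------------------
  if (nz > 1L) {
    we <- pad_y(w, grid)
    uzf <- 0.5 * (u[, , izm, drop = FALSE] + u)
    wxf <- 0.5 * (w[ixm, , , drop = FALSE] + w)
    Fx <- uzf * wxf                                  # at x-face/z-face
    advw <- (Fx[ixp, , , drop = FALSE] - Fx) / h[1]
    if (wall) {
      wyf <- 0.5 * (we[, 1:(ny + 1L), , drop = FALSE] +
                    we[, 2:(ny + 2L), , drop = FALSE])       # (nx, ny+1, nz)
      vzf <- 0.5 * (v[, , izm, drop = FALSE] + v)            # (nx, ny+1, nz)
      Fy <- wyf * vzf
      advw <- advw + (Fy[, 2:(ny + 1L), , drop = FALSE] -
                      Fy[, 1:ny, , drop = FALSE]) / h[2]
    } else {
      wyf <- 0.5 * (w[, grid$iym, , drop = FALSE] + w)
      vzf <- 0.5 * (v[, , izm, drop = FALSE] + v)
      Fy <- wyf * vzf
      advw <- advw + (Fy[, grid$iyp, , drop = FALSE] - Fy) / h[2]
    }
    wc <- 0.5 * (w + w[, , izp, drop = FALSE])       # w at centers
    Fz <- wc * wc
    advw <- advw + (Fz - Fz[, , izm, drop = FALSE]) / h[3]
    lapw <- (w[ixp, , , drop = FALSE] - 2 * w + w[ixm, , , drop = FALSE]) / h[1]^2 +
            (we[, 3:(ny + 2L), , drop = FALSE] - 2 * w +
             we[, 1:ny, , drop = FALSE]) / h[2]^2 +
            (w[, , izp, drop = FALSE] - 2 * w + w[, , izm, drop = FALSE]) / h[3]^2
    Hw <- -advw + nu * lapw
  } else {
    Hw <- array(0, dim(w))
  }
  list(u = Hu, v = Hv, w = Hw)
}

#' One Runge-Kutta time step
#'
#' Advances the state by `dt` with the three-stage low-storage scheme:
#' per stage, explicit advection + diffusion in an Adams-Bashforth-like
#' combination, fringe forces weighted by the stage advancement fraction,
#' pressure projection to the divergence-free subspace, and (optionally)
#' a uniform body force enforcing a constant bulk velocity.
#'
#' @param state a `velocity_field` (divergence within tolerance).
#' @param grid the [stag_grid()].
#' @param cfg a [solver_config()].
#' @param regions list of [fringe_region()]s.
#' @param dt time step.
#' @param plan a [poisson_plan()] for the grid.
#' @return the advanced `velocity_field` (time stamp `state$t + dt`).
#' @export
rk3_step <- function(state, grid, cfg, regions = list(), dt, plan) {
  g <- cfg$rk$gamma; z <- cfg$rk$zeta; a <- cfg$rk$alpha
  Hold <- NULL
  t0 <- state$t
  for (k in 1:3) {
    H <- momentum_rhs(state, grid, cfg$nu)
    du <- dt * g[k] * H$u
    dv <- dt * g[k] * H$v
    dw <- dt * g[k] * H$w
    if (k > 1L) {
      du <- du + dt * z[k] * Hold$u
      dv <- dv + dt * z[k] * Hold$v
      dw <- dw + dt * z[k] * Hold$w
    }
    for (rg in regions) {
      Fr <- fringe_force(state, rg, k, dt, grid)
      du <- du + a[k] * dt * Fr$u
      dv <- dv + a[k] * dt * Fr$v
      dw <- dw + a[k] * dt * Fr$w
    }
    state$u <- state$u + du
    state$v <- state$v + dv
    if (!grid$quasi2d) state$w <- state$w + dw
    state <- enforce_walls(state, grid)
    state <- project(state, grid, plan, a[k] * dt)
    if (!is.na(cfg$bulk_u))
      state$u <- state$u + (cfg$bulk_u - mean(state$u))
    state$t <- t0 + sum(a[1:k]) * dt
    Hold <- H
  }
  if (!all(is.finite(state$u)) || !all(is.finite(state$v)))
    stop(sprintf("solver diverged (NaN/Inf) at t = %.6g", state$t))
  state$t <- t0 + dt
  state
}

cfl_dt <- function(state, grid, cfg) {
  h <- grid$spacing
  umax <- max(abs(state$u), 1e-12) / h[1]
  vmax <- max(abs(state$v), 1e-12) / h[2]
  wmax <- if (grid$quasi2d) 0 else max(abs(state$w)) / h[3]
  adv <- cfg$cfl / (umax + vmax + wmax)
  visc <- 0.2 * min(h[seq_len(if (grid$quasi2d) 2 else 3)])^2 / cfg$nu
  min(adv, visc)
}

#' Advance the state to a target time
#'
#' Repeated [rk3_step()]s, the last one shortened to land exactly on
#' `t_target` (the forecast operator between two Kalman updates).
#'
#' @param state a `velocity_field`.
#' @param t_target target time (`>= state$t`).
#' @param grid,cfg,regions,plan as in [rk3_step()].
#' @param each_step optional `function(state)` called after every full step
#'   (probe recording, logging).
#' @return the forecast `velocity_field` at `t_target`.
#' @export
advance_to <- function(state, t_target, grid, cfg, regions = list(),
                       plan = NULL, each_step = NULL) {
  if (is.null(plan)) plan <- poisson_plan(grid)
  if (t_target < state$t - 1e-12) stop("t_target lies in the past")
  repeat {
    rem <- t_target - state$t
    if (rem <= 1e-12) break
    dt <- if (is.na(cfg$dt)) cfl_dt(state, grid, cfg) else cfg$dt
    dt <- min(dt, rem)
    state <- rk3_step(state, grid, cfg, regions, dt, plan)
    if (!is.null(each_step)) each_step(state)
  }
  state$t <- t_target
  state
}
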