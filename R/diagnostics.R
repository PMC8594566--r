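# Flow statistics used for validation: wall friction scales, wall units,
# turbulent kinetic energy, Reynolds-stress profiles and vorticity.

#' Friction Reynolds number and friction velocity
#'
#' The wall velocity gradient is evaluated with a one-sided first-order
#' difference from the first off-wall u-node (no-slip wall value zero),
#' averaged over the wall plane(s); then
#' `U_tau = sqrt(nu |grad| u_ref / l_ref)` and
#' `Re_tau = U_tau l_ref / nu`.  For laminar Poiseuille flow with center
#' velocity `U` this reduces to the closed form `Re_tau = sqrt(2 U Re)`.
#'
#' @param field a `velocity_field` or an `n x 3` matrix of center
#'   velocities (e.g. a phase mean).
#' @param grid the [stag_grid()] (must have no-slip y walls).
#' @param cfg a [solver_config()] providing `nu`, `u_ref`, `l_ref`.
#' @param walls `"both"` (default, the two wall averages combined),
#'   `"bottom"` or `"top"`.
#' @return list with `re_tau`, `u_tau` and the wall gradient `dudy`.
#' @export
friction_reynolds <- function(field, grid, cfg, walls = "both") {
  if (!grid$wall_y) stop("no no-slip wall configured on this grid")
  ny <- grid$cells[2]
  if (inherits(field, "velocity_field")) {
    Xc <- interpolate_to_centers(field, grid)
  } else Xc <- field
  ux <- array(Xc[, 1], grid$cells)
  dy2 <- grid$spacing[2] / 2              # first center sits at dy/2
  g_bot <- mean(abs(ux[, 1, ])) / dy2
  g_top <- mean(abs(ux[, ny, ])) / dy2
  grad <- switch(walls, both = 0.5 * (g_bot + g_top), bottom = g_bot,
                 top = g_top, stop("unknown walls option"))
  u_tau <- sqrt(cfg$nu * grad * cfg$u_ref / cfg$l_ref)
  list(re_tau = u_tau * cfg$l_ref / cfg$nu, u_tau = u_tau, dudy = grad)
}

#' Scale a profile to wall units
#'
#' `u+ = u / U_tau`, `y+ = y U_tau / nu`.
#'
#' @param y wall distances.
#' @param u velocity component parallel to the wall.
#' @param u_tau friction velocity (`> 0`).
#' @param nu kinematic viscosity.
#' @return data.frame with `y_plus`, `u_plus`.
#' @export
to_wall_units <- function(y, u, u_tau, nu) {
  if (u_tau <= 0) stop("u_tau must be positive")
  data.frame(y_plus = y * u_tau / nu, u_plus = u / u_tau)
}

#' Turbulent kinetic energy within a volume of interest
#'
#' Volume average over the masked cells of half the trace of the
#' fluctuation covariance.  The D regularization is excluded by default so
#' the value measures physical fluctuations (set `include_D = TRUE` for
#' the regularized variant).
#'
#' @param moments a [running_moments()] with at least one pulse.
#' @param phase phase index.
#' @param mask logical vector over cells (or `NULL` for the whole domain).
#' @param include_D include the D regularization term.
#' @return scalar TKE (velocity-squared units).
#' @export
tke <- function(moments, phase = 1L, mask = NULL, include_D = FALSE) {
  cov <- finalize_covariance(moments, phase, include_D = include_D)
  tr <- rowSums(cov[, 1:3, drop = FALSE])
  if (!is.null(mask)) {
    if (!any(mask)) stop("empty volume mask")
    tr <- tr[mask]
  }
  0.5 * mean(tr)
}

#' Reynolds-stress (covariance) profile along a y grid line
#'
#' Extracts the fluctuation covariance components at the cells nearest to
#' `(x, z)` across the full y extent.
#'
#' @param moments a [running_moments()].
#' @param grid the grid.
#' @param x,z line position (length units).
#' @param phase phase index.
#' @param include_D include the D regularization term.
#' @return data.frame with `y` and columns `xx, yy, zz, xy, xz, yz`.
#' @export
rss_profile <- function(moments, grid, x, z = grid$zc[1], phase = 1L,
                        include_D = FALSE) {
  if (x < grid$origin[1] || x > grid$origin[1] + grid$extent[1])
    stop("profile line outside the domain")
  i <- which.min(abs(grid$xc - x))
  k <- which.min(abs(grid$zc - z))
  idx <- cell_index(i, seq_len(grid$cells[2]), k, grid$cells)
  cov <- finalize_covariance(moments, phase, nodes = idx,
                             include_D = include_D)
  out <- data.frame(y = grid$yc, cov)
  names(out) <- c("y", "xx", "yy", "zz", "xy", "xz", "yz")
  out
}

#' Mean-velocity profile along a y grid line
#'
#' @inheritParams rss_profile
#' @return data.frame with `y`, `ux`, `uy`, `uz`.
#' @export
mean_profile <- function(moments, grid, x, z = grid$zc[1], phase = 1L) {
  i <- which.min(abs(grid$xc - x))
  k <- which.min(abs(grid$zc - z))
  idx <- cell_index(i, seq_len(grid$cells[2]), k, grid$cells)
  mu <- phase_mean(moments, phase)[idx, , drop = FALSE]
  data.frame(y = grid$yc, ux = mu[, 1], uy = mu[, 2], uz = mu[, 3])
}

#' Span-wise vorticity at cell centers
#'
#' `omega_z = d(uy)/dx - d(ux)/dy` by central differences of the
#' center-interpolated velocity (one-sided at walls).
#'
#' @param field a `velocity_field`.
#' @param grid the grid.
#' @return array of dimension `cells`.
#' @export
vorticity <- function(field, grid) {
  cells <- grid$cells
  Xc <- interpolate_to_centers(field, grid)
  ux <- array(Xc[, 1], cells); uy <- array(Xc[, 2], cells)
  h <- grid$spacing
  dvdx <- (uy[grid$ixp, , , drop = FALSE] -
           uy[grid$ixm, , , drop = FALSE]) / (2 * h[1])
  ny <- cells[2]
  dudy <- array(0, cells)
  if (grid$wall_y) {
    dudy[, 2:(ny - 1), ] <- (ux[, 3:ny, , drop = FALSE] -
                             ux[, 1:(ny - 2), , drop = FALSE]) / (2 * h[2])
    # one-sided toward the wall, consistent with a zero wall value
    dudy[, 1, ] <- (ux[, 2, ] - (-ux[, 1, ])) / (2 * h[2])
    dudy[, ny, ] <- ((-ux[, ny, ]) - ux[, ny - 1, ]) / (2 * h[2])
  } else {
    dudy <- (ux[, grid$iyp, , drop = FALSE] -
             ux[, grid$iym, , drop = FALSE]) / (2 * h[2])
  }
  dvdx - dudy
}

#' Estimate a dominant oscillation period from a probe signal
#'
#' Detrends, Hann-windows and Fourier-transforms the signal, locates the
#' spectral peak and refines it by local parabolic interpolation of the
#' log-power; used to measure the vortex-shedding period from a wake probe
#' recorded over many cycles.
#'
#' @param x numeric signal sampled at constant rate.
#' @param dt sampling interval.
#' @return the period `1 / f_peak` (time units).
#' @export
estimate_period <- function(x, dt) {
  n <- length(x)
  stopifnot(n >= 16)
  x <- x - mean(x)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))   # Hann
  P <- Mod(stats::fft(x * w))^2
  half <- floor(n / 2)
  k <- which.max(P[2:half]) + 1L                        # skip DC
  logP <- log(pmax(P, 1e-300))
  if (k > 2 && k < half) {
    a <- logP[k - 1]; b <- logP[k]; cc <- logP[k + 1]
    delta <- 0.5 * (a - cc) / (a - 2 * b + cc)
  } else delta <- 0
  f <- (k - 1 + delta) / (n * dt)
  1 / f
}
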