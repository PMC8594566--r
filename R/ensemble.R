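# Phase-indexed running ensemble statistics over pulses.  The ensemble of a
# pulsatile flow is built from successive pulses: realization r of phase phi
# lives at t = t_phi + (r - 1) T.  Running means and deviation-product sums
# are accumulated one-pass (Welford) per grid node and phase; the finalized
# forecast covariance is the D-regularized biased form
# p^f = (D + sum of outer products) / s, which equals D at s = 1 and loses
# the D influence as 1/s.

#' Phase schedule of a pulsatile (or statistically steady) flow
#'
#' @param T pulse period (time units).
#' @param n_phi number of phases the period is divided into.
#' @param t_phi phase times, strictly increasing with `t_phi[n_phi] == T`;
#'   defaults to equal intervals `T * (1:n_phi) / n_phi`.
#' @param dtau update interval for steady-state mode (`n_phi == 1`); the
#'   time-average ensemble then uses samples every `dtau` (defaults to `T`).
#' @return object of class `phase_schedule`.
#' @export
phase_schedule <- function(T, n_phi, t_phi = NULL, dtau = NULL) {
  n_phi <- as.integer(n_phi)
  stopifnot(T > 0, n_phi >= 1L)
  if (is.null(t_phi)) t_phi <- T * seq_len(n_phi) / n_phi
  stopifnot(length(t_phi) == n_phi, all(diff(t_phi) > 0),
            t_phi[1] > 0, abs(t_phi[n_phi] - T) < 1e-12 * max(T, 1))
  steady <- (n_phi == 1L)
  if (steady) {
    if (is.null(dtau)) dtau <- T
    stopifnot(dtau > 0)
    T <- dtau
    t_phi <- dtau
  }
  structure(list(T = T, n_phi = n_phi, t_phi = t_phi,
                 steady = steady, dtau = if (steady) dtau else NA),
            class = "phase_schedule")
}

#' Absolute time of pulse `r`, phase `phi`
#' @param schedule a [phase_schedule()].
#' @param pulse pulse index `r` (1-based).
#' @param phase phase index.
#' @return `t_phi + (r - 1) * T`.
#' @export
phase_time <- function(schedule, pulse, phase) {
  stopifnot(phase >= 1L, phase <= schedule$n_phi)
  schedule$t_phi[phase] + (pulse - 1) * schedule$T
}

#' Running per-node, per-phase ensemble moments
#'
#' @param n_nodes number of grid nodes tracked.
#' @param n_phi number of phases.
#' @param D diagonal regularization (scalar or length-3, variance units)
#'   added to the deviation-product sum before division by the pulse count;
#'   keeps the finalized covariance positive definite while the ensemble is
#'   small.
#' @return object of class `running_moments`.
#' @export
running_moments <- function(n_nodes, n_phi, D = 10) {
  D <- rep(as.numeric(D), length.out = 3L)
  stopifnot(all(D >= 0))
  structure(list(count = integer(n_phi),
                 mean = array(0, c(n_nodes, 3, n_phi)),
                 m2 = array(0, c(n_nodes, 6, n_phi)),   # xx yy zz xy xz yz
                 D = D, n_nodes = n_nodes, n_phi = n_phi),
            class = "running_moments")
}

#' One-pass moment update with a new pulse realization
#'
#' Numerically stable Welford update of the running mean and
#' deviation-product sum of phase `phase` with the center-collocated
#' velocities of one pulse.
#'
#' @param moments a [running_moments()].
#' @param X matrix `n_nodes x 3` (center velocities) or a
#'   `velocity_field` with `grid` supplied.
#' @param phase phase index.
#' @param grid grid for interpolating a `velocity_field`.
#' @return the updated `running_moments`.
#' @export
update_moments <- function(moments, X, phase, grid = NULL) {
  if (inherits(X, "velocity_field")) {
    if (is.null(grid)) stop("grid required to interpolate a velocity_field")
    X <- interpolate_to_centers(X, grid)
  }
  phase <- as.integer(phase)
  if (phase < 1L || phase > moments$n_phi) stop("phase index out of range")
  stopifnot(nrow(X) == moments$n_nodes)
  s <- moments$count[phase] + 1L
  mu <- matrix(moments$mean[, , phase], moments$n_nodes, 3)
  d1 <- X - mu
  mu <- mu + d1 / s
  d2 <- X - mu
  M <- matrix(moments$m2[, , phase], moments$n_nodes, 6)
  M[, 1] <- M[, 1] + d1[, 1] * d2[, 1]
  M[, 2] <- M[, 2] + d1[, 2] * d2[, 2]
  M[, 3] <- M[, 3] + d1[, 3] * d2[, 3]
  M[, 4] <- M[, 4] + d1[, 1] * d2[, 2]
  M[, 5] <- M[, 5] + d1[, 1] * d2[, 3]
  M[, 6] <- M[, 6] + d1[, 2] * d2[, 3]
  moments$count[phase] <- s
  moments$mean[, , phase] <- mu
  moments$m2[, , phase] <- M
  moments
}

#' Finalized D-regularized forecast covariance
#'
#' `p^f = (D + sum of deviation outer products) / s` per node: equals `D`
#' exactly at `s = 1`; the D contribution decays as `1/s`.
#'
#' @param moments a [running_moments()].
#' @param phase phase index.
#' @param nodes optional node subset (indices).
#' @param include_D set `FALSE` for the raw biased sample covariance.
#' @return matrix `n x 6` (`xx, yy, zz, xy, xz, yz`).
#' @export
finalize_covariance <- function(moments, phase, nodes = NULL,
                                include_D = TRUE) {
  s <- moments$count[phase]
  if (s < 1L) stop("no pulses accumulated for this phase (s = 0)")
  M <- matrix(moments$m2[, , phase], moments$n_nodes, 6)
  if (!is.null(nodes)) M <- M[nodes, , drop = FALSE]
  if (include_D) {
    M[, 1] <- M[, 1] + moments$D[1]
    M[, 2] <- M[, 2] + moments$D[2]
    M[, 3] <- M[, 3] + moments$D[3]
  }
  M / s
}

#' Phase mean of the running moments
#' @param moments a [running_moments()].
#' @param phase phase index.
#' @return matrix `n_nodes x 3`.
#' @export
phase_mean <- function(moments, phase) {
  if (moments$count[phase] < 1L) stop("no pulses accumulated (s = 0)")
  matrix(moments$mean[, , phase], moments$n_nodes, 3)
}

#' Reynolds decomposition: fluctuation of a realization about the phase mean
#'
#' @param X matrix `n_nodes x 3` (one realization, center velocities).
#' @param moments a [running_moments()].
#' @param phase phase index.
#' @return matrix `n_nodes x 3` of fluctuations `X - <u>_phi`.
#' @export
reynolds_decompose <- function(X, moments, phase) {
  X - phase_mean(moments, phase)
}

#' Phase-averaged observation statistics from per-pulse samples
#'
#' Per-voxel mean and biased (divisor `p`) covariance per phase, the
#' voxel-and-phase-averaged observation statistics of a pulsatile
#' measurement.
#'
#' @param samples list of length `n_phi`; each element an array
#'   `p x m_v x 3` of per-pulse voxel samples for that phase.
#' @param schedule the [phase_schedule()].
#' @param voxels the [voxel_grid()].
#' @param keep_samples retain the per-pulse samples in the set.
#' @return an [observation_set()].
#' @export
phase_average_samples <- function(samples, schedule, voxels,
                                  keep_samples = FALSE) {
  n_phi <- length(samples)
  stopifnot(n_phi == schedule$n_phi)
  p <- dim(samples[[1]])[1]
  m_v <- dim(samples[[1]])[2]
  if (is.null(p) || p < 1L) stop("empty phase group")
  mean_a <- array(0, c(m_v, 3, n_phi))
  cov_a <- array(0, c(m_v, 6, n_phi))
  for (phi in seq_len(n_phi)) {
    A <- samples[[phi]]
    stopifnot(dim(A)[1] == p, dim(A)[2] == m_v)
    mu <- apply(A, c(2, 3), mean)
    mean_a[, , phi] <- mu
    dev <- sweep(A, c(2, 3), mu)
    dx <- matrix(dev[, , 1], p, m_v); dy <- matrix(dev[, , 2], p, m_v)
    dz <- matrix(dev[, , 3], p, m_v)
    cov_a[, 1, phi] <- colMeans(dx * dx)
    cov_a[, 2, phi] <- colMeans(dy * dy)
    cov_a[, 3, phi] <- colMeans(dz * dz)
    cov_a[, 4, phi] <- colMeans(dx * dy)
    cov_a[, 5, phi] <- colMeans(dx * dz)
    cov_a[, 6, phi] <- colMeans(dy * dz)
  }
  observation_set(schedule, voxels, p, mean_a, cov_a,
                  samples = if (keep_samples) samples else NULL)
}
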