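# The stochastic ensemble Kalman analysis step in per-voxel block form.
#
# With cross-voxel and cross-node covariances assumed zero, the state-space
# Kalman gain K = P H^T (H P H^T + R)^-1 collapses voxel by voxel: for each
# active voxel v the innovation covariance is
#   S_v = h p^f h^T + r_v = (1/g_v^2) sum_g p^f_g + r_v      (3 x 3)
# and the correction a member node g receives from v is
#   p^f_g (1/g_v) S_v^-1 (d_v - h u^f).
# Contributions from the v_g voxels containing a node are combined with the
# interpolation weights Psi = 1/v_g; nodes outside every active voxel get
# zero correction.

#' Kalman filter configuration
#'
#' @param sampling how the per-update observation sample is drawn:
#'   `"cycle"` replays the stored per-pulse samples (pulse `s` uses stored
#'   sample `1 + (s - 1) mod p`); `"perturb"` draws
#'   `d ~ N(d_bar, r)` per voxel (perturbed observations); `"mean"` uses
#'   the phase mean itself (no perturbation).
#' @param seed integer seed for the perturbation stream (recorded in
#'   outputs).
#' @param reproject re-project the analysis state to the divergence-free
#'   subspace after each update.
#' @param max_pulses optional cap on the number of assimilated pulses.
#' @return object of class `kalman_config`.
#' @export
kalman_config <- function(sampling = c("cycle", "perturb", "mean"),
                          seed = 1L, reproject = TRUE, max_pulses = Inf) {
  sampling <- match.arg(sampling)
  structure(list(sampling = sampling, seed = as.integer(seed),
                 reproject = reproject, max_pulses = max_pulses),
            class = "kalman_config")
}

# Fast path: per-voxel gains for a whole phase.
# Xc: n x 3 forecast center velocities; pf: n x 6 finalized covariances;
# d: m_v x 3 observation sample; r: m_v x 6 observation covariance.
# Returns list(K = n x 3 node corrections, y = m_v x 3 solved innovations).
senkf_corrections <- function(Xc, pf, d, r, mapping) {
  g_v <- mapping$g_v
  pairs <- mapping$pairs
  # S_v = (1/g_v^2) sum_g p^f_g + r_v
  Ssum <- rowsum(pf[pairs$node, , drop = FALSE], pairs$voxel, reorder = TRUE)
  S <- Ssum / g_v^2 + r
  innov <- d - observe(Xc, mapping)
  y <- sym6_solve(S, innov)                       # S_v^-1 innovation
  # z_g = sum_{v in v_g} Psi_{g,v} (1/g_v) y_v ; then k_g = p^f_g z_g
  w <- (1 / (mapping$v_g[pairs$node] * g_v[pairs$voxel]))
  Z <- matrix(0, mapping$m_g, 3)
  acc <- rowsum(y[pairs$voxel, , drop = FALSE] * w, pairs$node,
                reorder = FALSE)
  Z[as.integer(rownames(acc)), ] <- acc
  K <- sym6_mv(pf, Z)
  list(K = K, y = y, S = S, innov = innov)
}

#' Kalman gain contributions of a single voxel
#'
#' Computes, for one active voxel, the innovation covariance
#' `S_v = h p^f h^T + r_v`, solves it symmetrically, and returns the
#' correction contribution `p^f_g (1/g_v) S_v^-1 (d_v - h u^f)` for each
#' member node (before the Psi interpolation across voxels).
#'
#' @param v index of the active voxel (position within `mapping$voxel_id`).
#' @param moments a [running_moments()] (forecast track).
#' @param obs an [observation_set()].
#' @param sample matrix `m_v x 3`, the observation sample in use.
#' @param mapping a [build_mapping()] result.
#' @param forecast `n x 3` matrix of forecast center velocities (or a
#'   `velocity_field` with `grid`).
#' @param phase phase index.
#' @param grid grid (when `forecast` is a field).
#' @return list with `nodes` (member node indices) and `contrib`
#'   (`g_v x 3` per-node contributions).
#' @export
voxel_gain <- function(v, moments, obs, sample, mapping, forecast, phase,
                       grid = NULL) {
  if (inherits(forecast, "velocity_field"))
    forecast <- interpolate_to_centers(forecast, grid)
  nodes <- mapping$pairs$node[mapping$pairs$voxel == v]
  gv <- mapping$g_v[v]
  stopifnot(gv >= 1L)
  pf <- finalize_covariance(moments, phase, nodes = nodes)
  S <- matrix(colSums(pf) / gv^2 + obs$cov[v, , phase], 1, 6)
  hforecast <- colMeans(forecast[nodes, , drop = FALSE])
  innov <- matrix(sample[v, ] - hforecast, 1, 3)
  y <- sym6_solve(S, innov)
  contrib <- sym6_mv(pf, matrix(y, gv, 3, byrow = TRUE)) / gv
  list(nodes = nodes, contrib = contrib, S = S, innov = innov)
}

#' Assemble per-voxel contributions into the node gain
#'
#' `k_g = sum_v Psi_{g,v} contrib_{v,g}` with `Psi = 1/v_g`; nodes outside
#' every active voxel get zero.
#'
#' @param contribs list of [voxel_gain()] results (all active voxels).
#' @param mapping the [build_mapping()] result.
#' @return matrix `m_g x 3` of node corrections.
#' @export
assemble_node_gain <- function(contribs, mapping) {
  K <- matrix(0, mapping$m_g, 3)
  for (cb in contribs) {
    psi <- 1 / mapping$v_g[cb$nodes]
    K[cb$nodes, ] <- K[cb$nodes, , drop = FALSE] + psi * cb$contrib
  }
  K
}

#' Apply the analysis update to a forecast field
#'
#' Adds the center-collocated correction to the staggered faces through the
#' adjoint of the center interpolation and, by default, re-projects so the
#' analysis state satisfies the discrete divergence constraint the forward
#' model assumes.
#'
#' @param forecast a `velocity_field`.
#' @param gain matrix `m_g x 3` of node corrections ([assemble_node_gain()]
#'   or the fast path inside [run_da()]).
#' @param grid the grid.
#' @param plan a [poisson_plan()] (required when `reproject`).
#' @param reproject restore the divergence tolerance after the update.
#' @return the analysis `velocity_field`.
#' @export
analysis_update <- function(forecast, gain, grid, plan = NULL,
                            reproject = TRUE) {
  dK <- centers_to_faces(gain, grid)
  forecast$u <- forecast$u + dK$u
  forecast$v <- forecast$v + dK$v
  if (!grid$quasi2d) forecast$w <- forecast$w + dK$w
  forecast <- enforce_walls(forecast, grid)
  if (reproject) {
    if (is.null(plan)) plan <- poisson_plan(grid)
    forecast <- project(forecast, grid, plan, 1)
  }
  forecast
}

# Draw/select the observation sample for pulse s, phase phi.
select_sample <- function(obs, s, phi, mode) {
  d_bar <- matrix(obs$mean[, , phi], dim(obs$mean)[1], 3)
  if (mode == "mean") return(d_bar)
  if (mode == "cycle" && !is.null(obs$samples)) {
    A <- obs$samples[[phi]]
    idx <- 1L + (s - 1L) %% dim(A)[1]
    return(matrix(A[idx, , ], dim(A)[2], 3))
  }
  # perturbed observations: d = d_bar + L z with L L^T = r (eigen sqrt,
  # negative numerical eigenvalues clipped at zero)
  r <- matrix(obs$cov[, , phi], dim(obs$cov)[1], 6)
  R <- sym6_full(r)
  m <- nrow(d_bar)
  z <- matrix(stats::rnorm(3 * m), m, 3)
  pert <- matrix(0, m, 3)
  nz <- which(rowSums(abs(r)) > 0)
  for (v in nz) {
    ev <- eigen(R[v, , ], symmetric = TRUE)
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 3)
    pert[v, ] <- as.numeric(L %*% z[v, ])
  }
  d_bar + pert
}

#' Run the full data-assimilation loop
#'
#' The driver: for each pulse `s` and phase `phi`, advance the forward
#' model to `t_phi + (s - 1) T`, accumulate the forecast into the running
#' phase moments, draw the observation sample, compute the per-voxel block
#' Kalman gain, apply the analysis update, and continue the integration
#' from the analysis state.  A separate analysis-moments track is kept for
#' diagnostics.
#'
#' @param case a case bundle (see [cylinder_case()], [channel_case()]),
#'   or any list with `grid`, `cfg`, `regions`, `ic`.
#' @param obs an [observation_set()].
#' @param pulses number of pulses to assimilate.
#' @param kcfg a [kalman_config()].
#' @param D diagonal regularization of the forecast covariance
#'   (velocity-squared units).
#' @param mapping optional precomputed [build_mapping()].
#' @param state optional initial `velocity_field` (defaults to the case's
#'   initial condition).
#' @param diagnostics_every record diagnostics every that many updates.
#' @param progress print a per-pulse log line.
#' @param resume optional checkpoint (list with `state`,
#'   `moments_forecast`, `moments_analysis` from a previous result or
#'   [write_results()] directory) to continue a run; `pulses` then counts
#'   additional pulses.
#' @return list with the final `state`, forecast and analysis
#'   `running_moments`, the `mapping`, a diagnostics data frame and a run
#'   manifest.
#' @export
run_da <- function(case, obs, pulses, kcfg = kalman_config(), D = 10,
                   mapping = NULL, state = NULL, diagnostics_every = 1L,
                   progress = FALSE, resume = NULL) {
  grid <- case$grid
  sched <- obs$schedule
  if (is.null(mapping)) mapping <- build_mapping(grid, obs$voxels)
  plan <- poisson_plan(grid)
  if (is.null(state)) state <- resume$state %||% case$ic(grid)
  n <- n_cells(grid)
  mom_f <- resume$moments_forecast %||% running_moments(n, sched$n_phi, D = D)
  mom_a <- resume$moments_analysis %||% running_moments(n, sched$n_phi, D = D)
  s0 <- max(mom_f$count)
  set.seed(kcfg$seed + s0)
  pulses <- min(pulses, kcfg$max_pulses)
  diag_rows <- list()
  upd <- 0L
  for (s in s0 + seq_len(pulses)) {
    for (phi in seq_len(sched$n_phi)) {
      t_n <- phase_time(sched, s, phi)
      state <- advance_to(state, t_n, grid, case$cfg, case$regions, plan)
      Xc <- interpolate_to_centers(state, grid)
      mom_f <- update_moments(mom_f, Xc, phi)
      pf <- finalize_covariance(mom_f, phi)
      d <- select_sample(obs, s, phi, kcfg$sampling)
      corr <- senkf_corrections(Xc, pf, d, matrix(obs$cov[, , phi],
                                                  mapping$m_v, 6), mapping)
      # the filter's analysis state lives on the (center-collocated) nodes;
      # the solver continues from its face-spread projection
      Xa <- Xc + corr$K
      mom_a <- update_moments(mom_a, Xa, phi)
      state <- analysis_update(state, corr$K, grid, plan,
                               reproject = kcfg$reproject)
      upd <- upd + 1L
      if (upd %% diagnostics_every == 0L) {
        diag_rows[[length(diag_rows) + 1L]] <- data.frame(
          t = t_n, pulse = s, phase = phi,
          ke = 0.5 * mean(rowSums(Xa^2)),
          gain_rms = sqrt(mean(corr$K^2)),
          max_div = max(abs(divergence(state, grid))))
      }
    }
    if (progress)
      message(sprintf("pulse %d/%d  t = %.4g  ke = %.4g", s, pulses,
                      state$t, kinetic_energy(state, grid)))
  }
  diagnostics <- do.call(rbind, diag_rows)
  manifest <- list(seed = kcfg$seed, sampling = kcfg$sampling,
                   reproject = kcfg$reproject, pulses = pulses,
                   D = D, n_phi = sched$n_phi, T = sched$T,
                   case = case$name %||% "custom")
  list(state = state, moments_forecast = mom_f, moments_analysis = mom_a,
       mapping = mapping, diagnostics = diagnostics, manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
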