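# Voxel observation model: voxel lattice definition, the discrete
# observation operator H built from node-in-voxel membership (equal node
# weights 1/g_v per voxel), and its transpose-like interpolation weights
# Psi (1/v_g per node) used to spread per-voxel Kalman corrections back to
# the grid nodes.

#' Voxel grid (observation lattice)
#'
#' A Cartesian lattice of cubic (per-axis edge `h`) voxels overlapping the
#' computational grid.  Observed data live on the active voxels; the active
#' mask expresses measurement windows.
#'
#' @param origin numeric length-3, corner of the first voxel.
#' @param h numeric length-3 (or scalar), voxel edge length per axis.
#' @param counts integer length-3, number of voxels per axis.
#' @param active logical array `counts` (or `NULL` for all active).
#' @param dw integer downsampling factor the lattice was built with
#'   (metadata; voxels of `(1+dw)^3` adjacent nodes).
#' @return object of class `voxel_grid`.
#' @export
voxel_grid <- function(origin, h, counts, active = NULL, dw = 0L) {
  h <- rep(as.numeric(h), length.out = 3L)
  counts <- as.integer(counts)
  stopifnot(all(h > 0), all(counts >= 1L), dw >= 0)
  if (is.null(active)) active <- array(TRUE, counts)
  stopifnot(all(dim(active) == counts))
  structure(list(origin = as.numeric(origin), h = h, counts = counts,
                 active = active, dw = as.integer(dw)),
            class = "voxel_grid")
}

# Per-axis membership of node coordinates in voxel intervals.
# Closed intervals: a node exactly on a shared interior border (within
# tol = 1e-9 h) belongs to both adjacent voxels.  Returns a 2-column matrix
# of candidate voxel indices (NA when absent / out of range).
axis_membership <- function(xc, origin, h, nv) {
  tol <- 1e-9
  t <- (xc - origin) / h
  j1 <- floor(t - tol) + 1
  j2 <- floor(t + tol) + 1
  j1[j1 < 1 | j1 > nv] <- NA
  j2[j2 < 1 | j2 > nv] <- NA
  j2[!is.na(j1) & !is.na(j2) & j1 == j2] <- NA
  cbind(j1, j2)
}

#' Build the grid-voxel mapping (discrete observation operator)
#'
#' Determines, for every cell-center node, the voxels containing it
#' (closed-boundary membership: a node exactly on a shared border belongs
#' to all adjacent voxels) and assembles the operator weight
#' `phi[v, g] = 1/g_v` (each row of H sums to one) and the interpolation
#' weight `Psi[g, v] = 1/v_g`.
#'
#' @param grid a [stag_grid()] (nodes are its cell centers).
#' @param voxels a [voxel_grid()] whose active window lies inside the domain.
#' @return object of class `grid_voxel_mapping` with elements
#'   `pairs` (data.frame `node`, `voxel` over active voxels),
#'   `g_v` (nodes per active voxel), `v_g` (voxels per node, 0 outside the
#'   window), `voxel_id` (linear indices of active voxels), `m_v`, `m_g`.
#' @export
build_mapping <- function(grid, voxels) {
  cells <- grid$cells
  nvx <- voxels$counts
  mx <- axis_membership(grid$xc, voxels$origin[1], voxels$h[1], nvx[1])
  my <- axis_membership(grid$yc, voxels$origin[2], voxels$h[2], nvx[2])
  mz <- axis_membership(grid$zc, voxels$origin[3], voxels$h[3], nvx[3])
  nid <- seq_len(prod(cells))
  I <- (nid - 1L) %% cells[1] + 1L
  J <- ((nid - 1L) %/% cells[1]) %% cells[2] + 1L
  K <- (nid - 1L) %/% (cells[1] * cells[2]) + 1L
  node <- integer(0); vx <- integer(0); vy <- integer(0); vz <- integer(0)
  for (cx in 1:2) for (cy in 1:2) for (cz in 1:2) {
    jx <- mx[I, cx]; jy <- my[J, cy]; jz <- mz[K, cz]
    ok <- !is.na(jx) & !is.na(jy) & !is.na(jz)
    if (any(ok)) {
      node <- c(node, nid[ok]); vx <- c(vx, jx[ok])
      vy <- c(vy, jy[ok]); vz <- c(vz, jz[ok])
    }
  }
  vlin <- vx + (vy - 1L) * nvx[1] + (vz - 1L) * nvx[1] * nvx[2]
  keep <- as.vector(voxels$active)[vlin]
  node <- node[keep]; vlin <- vlin[keep]
  voxel_id <- sort(unique(as.vector(which(voxels$active))))
  vput <- match(vlin, voxel_id)
  m_v <- length(voxel_id)
  g_v <- tabulate(vput, nbins = m_v)
  if (any(g_v == 0L))
    stop(sprintf("%d active voxel(s) contain no grid node (g_v = 0); ",
                 sum(g_v == 0L)),
         "check the window geometry against the grid")
  v_g <- tabulate(node, nbins = prod(cells))
  ord <- order(vput, node)
  structure(list(pairs = data.frame(node = node[ord], voxel = vput[ord]),
                 g_v = g_v, v_g = v_g, voxel_id = voxel_id,
                 m_v = m_v, m_g = prod(cells),
                 cells = cells, voxels = voxels),
            class = "grid_voxel_mapping")
}

#' @export
print.grid_voxel_mapping <- function(x, ...) {
  cat(sprintf("<grid_voxel_mapping> %d active voxels over %d nodes\n",
              x$m_v, x$m_g))
  cat(sprintf("  nodes/voxel g_v: %s; nodes inside window: %d (of %d)\n",
              paste(range(x$g_v), collapse = "-"), sum(x$v_g > 0), x$m_g))
  invisible(x)
}

#' Observe a velocity field on the voxel grid
#'
#' Center-interpolated velocity averaged with equal weights `1/g_v` over
#' the member nodes of each active voxel (the action of the h-blocks of
#' the observation operator).
#'
#' @param field a `velocity_field` or an `n_cells x 3` matrix of
#'   center-collocated velocities.
#' @param mapping a [build_mapping()] result.
#' @param grid the grid (required when `field` is a `velocity_field`).
#' @return matrix `m_v x 3` of per-voxel mean velocities.
#' @export
observe <- function(field, mapping, grid = NULL) {
  Xc <- if (inherits(field, "velocity_field")) {
    if (is.null(grid)) stop("grid required to interpolate a velocity_field")
    interpolate_to_centers(field, grid)
  } else field
  if (nrow(Xc) != mapping$m_g) stop("mapping/grid mismatch")
  S <- rowsum(Xc[mapping$pairs$node, , drop = FALSE], mapping$pairs$voxel,
              reorder = TRUE)
  unname(S / mapping$g_v)
}

#' Innovation: observation minus predicted observation
#'
#' @param sample matrix `m_v x 3`, the voxel observation sample.
#' @param forecast_obs matrix `m_v x 3`, [observe()] of the forecast.
#' @return matrix `m_v x 3`.
#' @export
innovation <- function(sample, forecast_obs) {
  stopifnot(all(dim(sample) == dim(forecast_obs)))
  sample - forecast_obs
}

#' Per-pulse voxel observation sample
#'
#' @param pulse pulse index `s`.
#' @param phase phase index.
#' @param d matrix `m_v x 3` of voxel velocities.
#' @return object of class `observation_sample`.
#' @export
observation_sample <- function(pulse, phase, d) {
  stopifnot_finite(d, "observation sample")
  structure(list(pulse = pulse, phase = phase, d = d),
            class = "observation_sample")
}

#' Voxel observation set
#'
#' Per-phase, per-voxel mean velocity and 3x3 covariance (stored as six
#' `xx, yy, zz, xy, xz, yz` columns), with the per-pulse samples optionally
#' retained.
#'
#' @param schedule a [phase_schedule()].
#' @param voxels the [voxel_grid()].
#' @param p number of pulses the statistics were computed from.
#' @param mean array `m_v x 3 x n_phi`.
#' @param cov array `m_v x 6 x n_phi` (symmetric PSD per voxel).
#' @param samples optional list (length `n_phi`) of arrays `p x m_v x 3`.
#' @return object of class `observation_set`.
#' @export
observation_set <- function(schedule, voxels, p, mean, cov, samples = NULL) {
  structure(list(schedule = schedule, voxels = voxels, p = p,
                 mean = mean, cov = cov, samples = samples),
            class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  cat(sprintf("<observation_set> %d voxels, %d phase(s), p = %d pulses%s\n",
              dim(x$mean)[1], dim(x$mean)[3], x$p,
              if (is.null(x$samples)) "" else " (samples retained)"))
  invisible(x)
}

# Expand m x 6 symmetric storage to an m x 3 x 3 array.
sym6_full <- function(S) {
  m <- nrow(S)
  A <- array(0, c(m, 3, 3))
  A[, 1, 1] <- S[, 1]; A[, 2, 2] <- S[, 2]; A[, 3, 3] <- S[, 3]
  A[, 1, 2] <- A[, 2, 1] <- S[, 4]
  A[, 1, 3] <- A[, 3, 1] <- S[, 5]
  A[, 2, 3] <- A[, 3, 2] <- S[, 6]
  A
}

# Symmetric 3x3 solve S y = b, vectorized over rows (S as m x 6, b as m x 3).
# Analytic adjugate; D > 0 in the forecast covariance guarantees
# positive-definiteness, so a vanishing determinant flags misconfiguration.
sym6_solve <- function(S, b) {
  a <- S[, 1]; bb <- S[, 2]; cc <- S[, 3]
  d <- S[, 4]; e <- S[, 5]; f <- S[, 6]
  A11 <- bb * cc - f * f
  A12 <- e * f - d * cc
  A13 <- d * f - bb * e
  A22 <- a * cc - e * e
  A23 <- d * e - a * f
  A33 <- a * bb - d * d
  det <- a * A11 + d * A12 + e * A13
  if (any(abs(det) < 1e-300))
    stop("singular innovation covariance S_v; is D set to a positive value?")
  cbind(A11 * b[, 1] + A12 * b[, 2] + A13 * b[, 3],
        A12 * b[, 1] + A22 * b[, 2] + A23 * b[, 3],
        A13 * b[, 1] + A23 * b[, 2] + A33 * b[, 3]) / det
}

# Symmetric 3x3 times vector, vectorized over rows.
sym6_mv <- function(S, x) {
  cbind(S[, 1] * x[, 1] + S[, 4] * x[, 2] + S[, 5] * x[, 3],
        S[, 4] * x[, 1] + S[, 2] * x[, 2] + S[, 6] * x[, 3],
        S[, 5] * x[, 1] + S[, 6] * x[, 2] + S[, 3] * x[, 3])
}
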