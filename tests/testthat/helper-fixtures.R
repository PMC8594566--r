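# Shared in-code fixtures: tiny grids, synthetic mappings and a dense
# state-space Kalman gain oracle used to cross-check the per-voxel block
# computation.

tiny_wall_grid <- function(nx = 8, ny = 8)
  stag_grid(c(4, 2, 1), c(nx, ny, 1), wall_y = TRUE)

tiny_periodic_grid <- function(n = 16)
  stag_grid(c(2 * pi, 2 * pi, 1), c(n, n, 1), wall_y = FALSE)

# Random mapping with disjoint voxels (no shared nodes), where the block
# form is algebraically identical to the dense gain.
random_disjoint_mapping <- function(m_g, n_vox, nodes_per) {
  stopifnot(sum(nodes_per) <= m_g)
  node <- sample.int(m_g, sum(nodes_per))
  voxel <- rep(seq_len(n_vox), nodes_per)
  v_g <- tabulate(node, m_g)
  structure(list(pairs = data.frame(node = node, voxel = voxel),
                 g_v = nodes_per, v_g = v_g, voxel_id = seq_len(n_vox),
                 m_v = n_vox, m_g = m_g),
            class = "grid_voxel_mapping")
}

sym6_to_mat <- function(row) {
  matrix(c(row[1], row[4], row[5],
           row[4], row[2], row[6],
           row[5], row[6], row[3]), 3, 3)
}

# Dense-oracle gain: K = P H^T (H P H^T + R)^-1 (d - H x) assembled on the
# full state space with block-diagonal P and the node-counting H.
dense_gain_oracle <- function(Xc, pf, d, r, mapping) {
  m_g <- mapping$m_g; m_v <- mapping$m_v
  node <- mapping$pairs$node; voxel <- mapping$pairs$voxel
  H <- matrix(0, 3 * m_v, 3 * m_g)
  for (q in seq_along(node)) for (i in 1:3)
    H[3 * (voxel[q] - 1) + i, 3 * (node[q] - 1) + i] <-
      1 / mapping$g_v[voxel[q]]
  P <- matrix(0, 3 * m_g, 3 * m_g)
  for (g in seq_len(m_g))
    P[3 * g - 2:0, 3 * g - 2:0] <- sym6_to_mat(pf[g, ])
  R <- matrix(0, 3 * m_v, 3 * m_v)
  for (v in seq_len(m_v))
    R[3 * v - 2:0, 3 * v - 2:0] <- sym6_to_mat(r[v, ])
  innov <- as.vector(t(d)) - H %*% as.vector(t(Xc))
  K <- P %*% t(H) %*% solve(H %*% P %*% t(H) + R, innov)
  matrix(K, m_g, 3, byrow = TRUE)
}

# Quick steady plug-flow case on a tiny wall grid (cheap forward model for
# filter-level tests).
tiny_case <- function(nx = 8, ny = 8, re = 100, dt = 0.01) {
  g <- tiny_wall_grid(nx, ny)
  list(name = "tiny", grid = g,
       cfg = solver_config(re = re, dt = dt),
       regions = list(), ic = function(grid) velocity_field(grid))
}
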