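# Pressure Poisson solver on the MAC grid.
#
# x and z are periodic, so the second-difference operator diagonalizes under
# the DFT with eigenvalues (2 cos(2 pi k / n) - 2)/h^2.  In y the operator is
# either periodic (fully spectral solve) or wall-bounded with homogeneous
# Neumann rows (tridiagonal solve per transverse wavenumber, vectorized
# Thomas algorithm with precomputed factorization).  The zero-wavenumber
# Neumann system is singular; it is regularized by pinning its first row
# (phi_1 = 0), which fixes the irrelevant pressure constant.

fft_x <- function(A, inverse = FALSE) {
  d <- dim(A)
  M <- matrix(A, d[1], d[2] * d[3])
  array(stats::mvfft(M, inverse = inverse), d)
}

fft_z <- function(A, inverse = FALSE) {
  d <- dim(A)
  if (d[3] == 1L) return(A)
  B <- aperm(A, c(3, 2, 1))
  M <- matrix(B, d[3], d[2] * d[1])
  B <- array(stats::mvfft(M, inverse = inverse), c(d[3], d[2], d[1]))
  aperm(B, c(3, 2, 1))
}

fft_y <- function(A, inverse = FALSE) {
  d <- dim(A)
  B <- aperm(A, c(2, 1, 3))
  M <- matrix(B, d[2], d[1] * d[3])
  B <- array(stats::mvfft(M, inverse = inverse), c(d[2], d[1], d[3]))
  aperm(B, c(2, 1, 3))
}

#' Precompute the Poisson solve plan for a grid
#'
#' @param grid a [stag_grid()].
#' @return opaque plan object consumed by [poisson_solve()].
#' @export
poisson_plan <- function(grid) {
  nx <- grid$cells[1]; ny <- grid$cells[2]; nz <- grid$cells[3]
  h <- grid$spacing
  lamx <- (2 * cos(2 * pi * (seq_len(nx) - 1) / nx) - 2) / h[1]^2
  lamz <- (2 * cos(2 * pi * (seq_len(nz) - 1) / nz) - 2) / h[3]^2
  if (!grid$wall_y) {
    lamy <- (2 * cos(2 * pi * (seq_len(ny) - 1) / ny) - 2) / h[2]^2
    L <- array(lamx, c(nx, ny, nz)) +
         array(rep(lamy, each = nx), c(nx, ny, nz)) +
         array(rep(lamz, each = nx * ny), c(nx, ny, nz))
    Linv <- 1 / L
    Linv[1, 1, 1] <- 0  # zero mode: mean of phi set to zero
    return(structure(list(type = "periodic", Linv = Linv, grid = grid),
                     class = "poisson_plan"))
  }
  # wall-bounded y: one tridiagonal system per (kx, kz) pair
  npair <- nx * nz
  lam <- as.vector(outer(lamx, lamz, "+"))        # npair values
  invdy2 <- 1 / h[2]^2
  # diagonals: Neumann rows at j = 1 and j = ny
  B <- matrix(lam, npair, ny) - 2 * invdy2
  B[, 1L] <- lam - invdy2
  B[, ny] <- lam - invdy2
  CU <- matrix(invdy2, npair, ny - 1L)  # upper coefficients
  CL <- matrix(invdy2, npair, ny - 1L)  # lower coefficients (row j couples j-1)
  # zero mode (kx = kz = 0 is pair 1): pin phi_1 = 0
  B[1L, 1L] <- 1; CU[1L, 1L] <- 0
  # Thomas factorization (RHS independent): m_j = B_j - CL_j * cp_{j-1}
  cp <- matrix(0, npair, ny - 1L)
  minv <- matrix(0, npair, ny)
  minv[, 1L] <- 1 / B[, 1L]
  for (j in seq_len(ny - 1L)) {
    cp[, j] <- CU[, j] * minv[, j]
    minv[, j + 1L] <- 1 / (B[, j + 1L] - CL[, j] * cp[, j])
  }
  structure(list(type = "wall", cp = cp, minv = minv, CL = CL,
                 nx = nx, ny = ny, nz = nz, grid = grid),
            class = "poisson_plan")
}

#' Solve the pressure Poisson equation `lap(phi) = rhs`
#'
#' @param plan a [poisson_plan()].
#' @param rhs cell-centered right-hand side array.
#' @return cell-centered solution array (pressure constant fixed arbitrarily).
#' @export
poisson_solve <- function(plan, rhs) {
  if (plan$type == "periodic") {
    Rh <- fft_y(fft_z(fft_x(rhs)))
    Ph <- Rh * plan$Linv
    n <- prod(dim(rhs))
    return(Re(fft_x(fft_z(fft_y(Ph, inverse = TRUE),
                          inverse = TRUE), inverse = TRUE)) / n)
  }
  nx <- plan$nx; ny <- plan$ny; nz <- plan$nz
  Rh <- fft_z(fft_x(rhs))                       # (nx, ny, nz) complex
  R <- matrix(aperm(Rh, c(1, 3, 2)), nx * nz, ny)
  R[1L, 1L] <- 0 + 0i                           # pinned zero-mode row
  # vectorized Thomas solve
  D <- matrix(0 + 0i, nx * nz, ny)
  D[, 1L] <- R[, 1L] * plan$minv[, 1L]
  for (j in seq_len(ny - 1L))
    D[, j + 1L] <- (R[, j + 1L] - plan$CL[, j] * D[, j]) * plan$minv[, j + 1L]
  X <- D
  for (j in rev(seq_len(ny - 1L)))
    X[, j] <- D[, j] - plan$cp[, j] * X[, j + 1L]
  Ph <- aperm(array(X, c(nx, nz, ny)), c(1, 3, 2))
  Re(fft_x(fft_z(Ph, inverse = TRUE), inverse = TRUE)) / (nx * nz)
}

#' Project a velocity field onto the divergence-free subspace
#'
#' Solves `lap(phi) = div(u)/dtp` and corrects `u <- u - dtp grad(phi)`;
#' wall v-faces are untouched (the homogeneous Neumann condition).  The
#' correction potential is accumulated into the pressure slot.
#'
#' @param field a `velocity_field`.
#' @param grid its [stag_grid()].
#' @param plan a matching [poisson_plan()].
#' @param dtp effective time increment of the correction (1 for a bare
#'   projection).
#' @return the projected field.
#' @export
project <- function(field, grid, plan, dtp = 1) {
  ny <- grid$cells[2]; nz <- grid$cells[3]
  div <- divergence(field, grid)
  phi <- poisson_solve(plan, div / dtp)
  h <- grid$spacing
  field$u <- field$u - dtp * (phi - phi[grid$ixm, , , drop = FALSE]) / h[1]
  if (grid$wall_y) {
    if (ny > 1L)
      field$v[, 2:ny, ] <- field$v[, 2:ny, , drop = FALSE] -
        dtp * (phi[, 2:ny, , drop = FALSE] -
               phi[, 1:(ny - 1L), , drop = FALSE]) / h[2]
  } else {
    field$v <- field$v - dtp * (phi - phi[, grid$iym, , drop = FALSE]) / h[2]
  }
  if (nz > 1L)
    field$w <- field$w - dtp * (phi - phi[, , grid$izm, drop = FALSE]) / h[3]
  field$p <- phi
  field
}
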