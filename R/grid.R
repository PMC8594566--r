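#' Staggered Cartesian grid (MAC layout)
#'
#' Uniform Cartesian grid with cell-centered pressure and face-centered
#' velocity components.  The x and z axes are always periodic; the y axis
#' is either wall-bounded (no-slip at `y = 0` and `y = Ly`) or periodic.
#' A quasi-2D configuration is obtained with `cells[3] == 1`, in which case
#' the span-wise axis collapses to a single periodic layer and the
#' span-wise velocity is identically zero.
#'
#' Cell centers sit at `origin + (i - 1/2) * spacing` (1-based storage,
#' 0-based geometry); x-faces of cell `i` at `origin + (i - 1) * spacing`.
#' For a wall-bounded y axis the `ny` cells carry `ny + 1` y-faces, the
#' first and last being the walls.
#'
#' @param extent numeric length-3, domain lengths per axis (length units).
#' @param cells  integer length-3, number of cells per axis.
#' @param wall_y logical, no-slip walls at the y extremes (otherwise periodic).
#' @param origin numeric length-3, coordinates of the domain corner.
#' @return object of class `stag_grid`.
#' @export
stag_grid <- function(extent, cells, wall_y = TRUE, origin = c(0, 0, 0)) {
  extent <- as.numeric(extent); cells <- as.integer(cells)
  stopifnot(length(extent) == 3L, length(cells) == 3L, all(extent > 0),
            all(cells >= 1L))
  if (any(cells[1:2] < 3L))
    stop("at least 3 cells are required on the x and y axes")
  spacing <- extent / cells
  nx <- cells[1L]; ny <- cells[2L]; nz <- cells[3L]
  g <- list(
    extent = extent, cells = cells, spacing = spacing, origin = origin,
    wall_y = wall_y,
    periodic = c(TRUE, !wall_y, TRUE),
    quasi2d = (nz == 1L),
    # cell-center and face coordinates per axis
    xc = origin[1] + (seq_len(nx) - 0.5) * spacing[1],
    yc = origin[2] + (seq_len(ny) - 0.5) * spacing[2],
    zc = origin[3] + (seq_len(nz) - 0.5) * spacing[3],
    xf = origin[1] + (seq_len(nx) - 1) * spacing[1],
    yf = origin[2] + (seq_len(ny + if (wall_y) 1L else 0L) - 1) * spacing[2],
    zf = origin[3] + (seq_len(nz) - 1) * spacing[3],
    # periodic shift index vectors
    ixp = c(seq_len(nx)[-1L], 1L), ixm = c(nx, seq_len(nx)[-nx]),
    iyp = c(seq_len(ny)[-1L], 1L), iym = c(ny, seq_len(ny)[-ny]),
    izp = if (nz > 1L) c(seq_len(nz)[-1L], 1L) else 1L,
    izm = if (nz > 1L) c(nz, seq_len(nz)[-nz]) else 1L)
  class(g) <- "stag_grid"
  g
}

#' @export
print.stag_grid <- function(x, ...) {
  cat(sprintf("<stag_grid> %d x %d x %d cells, extent %.4g x %.4g x %.4g\n",
              x$cells[1], x$cells[2], x$cells[3],
              x$extent[1], x$extent[2], x$extent[3]))
  cat(sprintf("  y axis: %s; %s\n",
              if (x$wall_y) "no-slip walls" else "periodic",
              if (x$quasi2d) "quasi-2D (single span-wise layer)" else "3D"))
  invisible(x)
}

n_cells <- function(grid) prod(grid$cells)

#' Zero velocity field on a staggered grid
#'
#' A `velocity_field` holds one array per velocity component at the
#' corresponding face family, a cell-centered pressure array and a time
#' stamp.  On a wall-bounded y axis the `v` array has `ny + 1` rows in y,
#' the first and last pinned to zero (the walls).
#'
#' @param grid a [stag_grid()].
#' @param t time stamp.
#' @return object of class `velocity_field`.
#' @export
velocity_field <- function(grid, t = 0) {
  nx <- grid$cells[1]; ny <- grid$cells[2]; nz <- grid$cells[3]
  nyv <- if (grid$wall_y) ny + 1L else ny
  f <- list(u = array(0, c(nx, ny, nz)),
            v = array(0, c(nx, nyv, nz)),
            w = array(0, c(nx, ny, nz)),
            p = array(0, c(nx, ny, nz)),
            t = t)
  class(f) <- "velocity_field"
  f
}

#' Build a velocity field from component functions
#'
#' Evaluates vectorized functions `fu(x, y, z)`, `fv`, `fw` at the natural
#' face locations of each component.
#'
#' @param grid a [stag_grid()].
#' @param fu,fv,fw functions of `(x, y, z)` returning the component value;
#'   `NULL` leaves the component zero.
#' @param t time stamp.
#' @return a `velocity_field`.
#' @export
field_from_fun <- function(grid, fu = NULL, fv = NULL, fw = NULL, t = 0) {
  f <- velocity_field(grid, t)
  if (!is.null(fu)) f$u[] <- eval_on(grid, "u", fu)
  if (!is.null(fv)) f$v[] <- eval_on(grid, "v", fv)
  if (!is.null(fw) && !grid$quasi2d) f$w[] <- eval_on(grid, "w", fw)
  enforce_walls(f, grid)
}

# Evaluate f(x,y,z) on the face family of component comp ("u","v","w")
# or at cell centers ("c"); returns an array of matching shape.
eval_on <- function(grid, comp, f) {
  xs <- switch(comp, u = grid$xf, v = grid$xc, w = grid$xc, c = grid$xc)
  ys <- switch(comp, u = grid$yc, v = grid$yf, w = grid$yc, c = grid$yc)
  zs <- switch(comp, u = grid$zc, v = grid$zc, w = grid$zf, c = grid$zc)
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  X <- array(xs, c(nx, ny, nz))
  Y <- array(rep(ys, each = nx), c(nx, ny, nz))
  Z <- array(rep(zs, each = nx * ny), c(nx, ny, nz))
  A <- f(X, Y, Z)
  array(A, c(nx, ny, nz))
}

# Pin wall v-faces to zero (no-slip normal component).
enforce_walls <- function(field, grid) {
  if (grid$wall_y) {
    nyv <- dim(field$v)[2]
    field$v[, 1L, ] <- 0
    field$v[, nyv, ] <- 0
  }
  field
}

#' Impose no-slip walls on a velocity field
#'
#' Sets the wall-normal velocity to zero on the wall faces.  Tangential
#' components are handled by the ghost convention of the solver stencils
#' (mirror-negated ghosts so the interpolated wall velocity vanishes); this
#' function also exposes that ghost fill for inspection.
#'
#' @param field a `velocity_field`.
#' @param grid its [stag_grid()].
#' @return the field with wall faces zeroed.
#' @export
no_slip_walls <- function(field, grid) {
  if (!grid$wall_y) stop("no-slip walls requested on a periodic y axis")
  enforce_walls(field, grid)
}

# Tangential ghost pad in y: array (nx, ny+2, nz) with ghost rows such that
# the linear interpolation to the wall plane is zero (no-slip) or periodic.
pad_y <- function(A, grid) {
  d <- dim(A); nx <- d[1]; ny <- d[2]; nz <- d[3]
  E <- array(0, c(nx, ny + 2L, nz))
  E[, 2:(ny + 1L), ] <- A
  if (grid$wall_y) {
    E[, 1L, ] <- -A[, 1L, ]
    E[, ny + 2L, ] <- -A[, ny, ]
  } else {
    E[, 1L, ] <- A[, ny, ]
    E[, ny + 2L, ] <- A[, 1L, ]
  }
  E
}

#' Discrete divergence at cell centers
#'
#' Centered (two-point face difference) divergence of a staggered velocity
#' field, with periodic wrap on periodic axes.  After a projection step its
#' magnitude is at the solver tolerance in every interior cell.
#'
#' @param field a `velocity_field`.
#' @param grid its [stag_grid()].
#' @return array of dimension `cells` with the divergence at cell centers.
#' @export
divergence <- function(field, grid) {
  nx <- grid$cells[1]; ny <- grid$cells[2]; nz <- grid$cells[3]
  if (!all(dim(field$u) == c(nx, ny, nz)))
    stop("field/grid shape mismatch")
  h <- grid$spacing
  div <- (field$u[grid$ixp, , , drop = FALSE] - field$u) / h[1]
  if (grid$wall_y) {
    div <- div + (field$v[, 2:(ny + 1L), , drop = FALSE] -
                  field$v[, 1:ny, , drop = FALSE]) / h[2]
  } else {
    div <- div + (field$v[, grid$iyp, , drop = FALSE] - field$v) / h[2]
  }
  if (nz > 1L)
    div <- div + (field$w[, , grid$izp, drop = FALSE] - field$w) / h[3]
  div
}

#' Interpolate face velocities to cell centers
#'
#' Linear two-point average of each face-centered component to the cell
#' centers, exact for fields affine in each coordinate.  The collocated
#' center velocity is the state on which voxel averaging and the Kalman
#' correction operate.
#'
#' @param field a `velocity_field`.
#' @param grid its [stag_grid()].
#' @return matrix `n_cells x 3` of center velocities, ordered by linear
#'   cell index (x fastest, then y, then z).
#' @export
interpolate_to_centers <- function(field, grid) {
  nx <- grid$cells[1]; ny <- grid$cells[2]; nz <- grid$cells[3]
  if (!all(dim(field$u) == c(nx, ny, nz)))
    stop("field/grid shape mismatch")
  uc <- 0.5 * (field$u + field$u[grid$ixp, , , drop = FALSE])
  if (grid$wall_y) {
    vc <- 0.5 * (field$v[, 1:ny, , drop = FALSE] +
                 field$v[, 2:(ny + 1L), , drop = FALSE])
  } else {
    vc <- 0.5 * (field$v + field$v[, grid$iyp, , drop = FALSE])
  }
  wc <- if (nz > 1L) 0.5 * (field$w + field$w[, , grid$izp, drop = FALSE])
        else field$w
  cbind(as.vector(uc), as.vector(vc), as.vector(wc))
}

# Spread a center-collocated vector field (n x 3) to the staggered faces by
# the adjoint of the two-point center interpolation; wall v-faces stay zero.
centers_to_faces <- function(K, grid) {
  nx <- grid$cells[1]; ny <- grid$cells[2]; nz <- grid$cells[3]
  kx <- array(K[, 1], c(nx, ny, nz))
  ky <- array(K[, 2], c(nx, ny, nz))
  kz <- array(K[, 3], c(nx, ny, nz))
  f <- velocity_field(grid)
  f$u <- 0.5 * (kx[grid$ixm, , , drop = FALSE] + kx)
  if (grid$wall_y) {
    f$v[, 2:ny, ] <- 0.5 * (ky[, 1:(ny - 1L), , drop = FALSE] +
                            ky[, 2:ny, , drop = FALSE])
  } else {
    f$v <- 0.5 * (ky[, grid$iym, , drop = FALSE] + ky)
  }
  if (nz > 1L) f$w <- 0.5 * (kz[, , grid$izm, drop = FALSE] + kz)
  f
}

#' Volume-averaged kinetic energy of a field
#' @param field a `velocity_field`.
#' @param grid its [stag_grid()].
#' @return scalar, `mean(|u|^2)/2` over cell centers.
#' @export
kinetic_energy <- function(field, grid) {
  Xc <- interpolate_to_centers(field, grid)
  0.5 * mean(rowSums(Xc^2))
}

# Linear cell index helpers (x fastest, then y, then z).
cell_index <- function(i, j, k, cells)
  i + (j - 1L) * cells[1] + (k - 1L) * cells[1] * cells[2]

stopifnot_finite <- function(x, what = "field") {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what))
  invisible(TRUE)
}
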