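# Axisymmetric finite-volume grid and diffusion operators for the biology
# stage. Cells are rectangles in the (r, z) half-plane; every cell volume and
# face area carries the 2 pi r metric, so fluxes and averages are exact for
# the axisymmetric geometry.

#' Finite-volume grid for the reaction-diffusion stage
#'
#' Uniform tensor-product grid of cell-centered control volumes on the
#' axisymmetric cartilage domain (radius x thickness). \code{z} is depth from
#' the articular surface.
#'
#' @param nr,nz Number of cells radially / through the depth.
#' @param radius Cartilage radius (m).
#' @param thickness Cartilage thickness (m).
#' @return An object of class \code{kinetics_grid} with cell-center vectors
#'   \code{r}, \code{z} (length \code{nr*nz}, radial index fastest) and cell
#'   volumes \code{V}.
#' @export
kinetics_grid <- function(nr = 40, nz = 20, radius = 12.5e-3,
                          thickness = 1e-3) {
  stopifnot(nr >= 2, nz >= 2, radius > 0, thickness > 0)
  dr <- radius / nr; dz <- thickness / nz
  rc <- (seq_len(nr) - 0.5) * dr
  zc <- (seq_len(nz) - 0.5) * dz
  r <- rep(rc, times = nz)
  z <- rep(zc, each = nr)
  V <- 2 * pi * r * dr * dz
  structure(list(nr = nr, nz = nz, radius = radius, thickness = thickness,
                 dr = dr, dz = dz, r = r, z = z, V = V),
            class = "kinetics_grid")
}

#' @export
print.kinetics_grid <- function(x, ...) {
  cat(sprintf("Axisymmetric FV grid: %d x %d cells on %.3g mm x %.3g mm\n",
              x$nr, x$nz, 1e3 * x$radius, 1e3 * x$thickness))
  invisible(x)
}

# Symmetric FV diffusion operator. Returns list(Lap, b):
#   d/dt (V C) = -Lap C + b * c_bath
# Lap is PSD; b holds Dirichlet face conductances (zero without Dirichlet).
# D is a scalar or per-cell vector; face diffusivity is the harmonic mean.
# dirichlet: subset of c("top", "outer") where the ghost value is the bath
# concentration; all other boundaries are zero-flux.
.fv_laplacian <- function(grid, D, dirichlet = character(0)) {
  nr <- grid$nr; nz <- grid$nz; dr <- grid$dr; dz <- grid$dz
  N <- nr * nz
  if (length(D) == 1) D <- rep(D, N)
  idx <- function(i, j) i + (j - 1L) * nr
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  diag_acc <- numeric(N)
  b <- numeric(N)
  # radial internal faces between (i, j) and (i+1, j), at r = i*dr
  if (nr > 1) {
    for (j in seq_len(nz)) {
      i <- seq_len(nr - 1)
      a <- idx(i, j); bb <- idx(i + 1L, j)
      Dface <- 2 * D[a] * D[bb] / (D[a] + D[bb])
      A <- 2 * pi * (i * dr) * dz
      g <- Dface * A / dr
      ii <- c(ii, a, bb); jj <- c(jj, bb, a); xx <- c(xx, -g, -g)
      diag_acc[a] <- diag_acc[a] + g
      diag_acc[bb] <- diag_acc[bb] + g
    }
  }
  # axial internal faces between (i, j) and (i, j+1)
  if (nz > 1) {
    for (j in seq_len(nz - 1)) {
      i <- seq_len(nr)
      a <- idx(i, j); bb <- idx(i, j + 1L)
      Dface <- 2 * D[a] * D[bb] / (D[a] + D[bb])
      A <- 2 * pi * grid$r[a] * dr
      g <- Dface * A / dz
      ii <- c(ii, a, bb); jj <- c(jj, bb, a); xx <- c(xx, -g, -g)
      diag_acc[a] <- diag_acc[a] + g
      diag_acc[bb] <- diag_acc[bb] + g
    }
  }
  # Dirichlet ghosts: top surface (j = 1) and outer edge (i = nr)
  if ("top" %in% dirichlet) {
    a <- idx(seq_len(nr), 1L)
    g <- D[a] * (2 * pi * grid$r[a] * dr) / (dz / 2)
    diag_acc[a] <- diag_acc[a] + g
    b[a] <- b[a] + g
  }
  if ("outer" %in% dirichlet) {
    a <- idx(nr, seq_len(nz))
    g <- D[a] * (2 * pi * grid$radius * dz) / (dr / 2)
    diag_acc[a] <- diag_acc[a] + g
    b[a] <- b[a] + g
  }
  Lap <- Matrix::sparseMatrix(i = c(ii, seq_len(N)), j = c(jj, seq_len(N)),
                              x = c(xx, diag_acc), dims = c(N, N))
  list(Lap = Matrix::forceSymmetric(Lap), b = b)
}

# Backward-Euler factorization for (V/dt) C_new + Lap C_new = (V/dt) C + b*cb
.fv_factor <- function(grid, lap, dt) {
  M <- Matrix::Diagonal(x = grid$V / dt) + lap$Lap
  list(ch = Matrix::Cholesky(M, LDL = FALSE), b = lap$b,
       Vdt = grid$V / dt)
}

.fv_solve <- function(fac, C, c_bath) {
  rhs <- fac$Vdt * C + fac$b * c_bath
  as.numeric(Matrix::solve(fac$ch, rhs))
}
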