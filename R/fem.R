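#' Classical baselines: linear/bilinear FEM and second-order FDM
#'
#' Conventional discretizations assembled on the same node lattices as the
#' meshfree method, used as comparison baselines in the verification
#' experiments. They return the same `efgm_system` shape (sparse `M`, `K`)
#' so the time integrators apply unchanged.
#'
#' @name baselines
#' @keywords internal
NULL

#' 1D linear finite elements on a uniform lattice
#'
#' Consistent tridiagonal mass matrix and stiffness with natural (zero-flux)
#' ends.
#'
#' @param n number of nodes.
#' @param h node spacing, mm.
#' @param sigma conductivity (enters K).
#' @return an `efgm_system`-shaped list with `M`, `K`.
#' @export
fem1d_system <- function(n, h, sigma) {
  stopifnot(n >= 3)
  e <- rep(1, n - 1)
  M <- Matrix::bandSparse(n, k = c(-1, 0, 1),
                          diagonals = list(h / 6 * e,
                                           c(h / 3, rep(2 * h / 3, n - 2), h / 3),
                                           h / 6 * e), symmetric = FALSE)
  K <- Matrix::bandSparse(n, k = c(-1, 0, 1),
                          diagonals = list(-sigma / h * e,
                                           sigma / h * c(1, rep(2, n - 2), 1),
                                           -sigma / h * e), symmetric = FALSE)
  structure(list(M = Matrix::forceSymmetric(M), K = Matrix::forceSymmetric(K),
                 n_quad = NA_integer_,
                 config = list(method = "fem1d", h = h, sigma = sigma)),
            class = "efgm_system")
}

#' 1D second-order finite differences on a uniform lattice
#'
#' Three-point Laplacian with mirror (zero-flux) end conditions; the mass
#' matrix is the identity scaled by nothing (collocation).
#'
#' @inheritParams fem1d_system
#' @return an `efgm_system`-shaped list; `K` here is -sigma * Laplacian so the
#'   common update v' = -M^-1 K v applies.
#' @export
fdm1d_system <- function(n, h, sigma) {
  stopifnot(n >= 3)
  e <- rep(1, n - 1)
  K <- Matrix::bandSparse(n, k = c(-1, 0, 1),
                          diagonals = list(-sigma / h^2 * e,
                                           sigma / h^2 * rep(2, n),
                                           -sigma / h^2 * e), symmetric = FALSE)
  K <- as(K, "CsparseMatrix")
  K[1, 2] <- -2 * sigma / h^2      # mirror node
  K[n, n - 1] <- -2 * sigma / h^2
  structure(list(M = Matrix::Diagonal(n), K = K, n_quad = NA_integer_,
                 config = list(method = "fdm1d", h = h, sigma = sigma)),
            class = "efgm_system")
}

#' 2D bilinear finite elements on a uniform lattice
#'
#' Bilinear quadrilateral elements on the cells of the node lattice, with the
#' same tensor-product Gauss rule as the meshfree assembly for a like-for-like
#' comparison. Natural boundary conditions (no essential rows).
#'
#' @param nx,ny nodes per axis.
#' @param hx,hy spacings, mm.
#' @param sigma isotropic conductivity.
#' @param points_per_axis Gauss order used for the element integrals.
#' @return an `efgm_system`-shaped list with sparse `M`, `K`.
#' @export
fem2d_system <- function(nx, ny, hx, hy, sigma, points_per_axis = 4) {
  gl <- pracma::gaussLegendre(points_per_axis, -1, 1)
  Mloc <- matrix(0, 4, 4); Kloc <- matrix(0, 4, 4)
  jac <- hx * hy / 4
  for (a in seq_along(gl$x)) for (b in seq_along(gl$x)) {
    xi <- gl$x[a]; eta <- gl$x[b]; w <- gl$w[a] * gl$w[b]
    Nf <- c((1 - xi) * (1 - eta), (1 + xi) * (1 - eta),
            (1 + xi) * (1 + eta), (1 - xi) * (1 + eta)) / 4
    dNdxi <- c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)) / 4 * (2 / hx)
    dNdeta <- c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi)) / 4 * (2 / hy)
    Mloc <- Mloc + w * jac * tcrossprod(Nf)
    Kloc <- Kloc + w * jac * sigma * (tcrossprod(dNdxi) + tcrossprod(dNdeta))
  }
  N <- nx * ny
  nid <- function(i, j) (j - 1L) * nx + i      # column-major lattice
  ncell <- (nx - 1L) * (ny - 1L)
  ii <- integer(16L * ncell); jj <- integer(16L * ncell)
  mm <- numeric(16L * ncell); kk <- numeric(16L * ncell)
  p <- 0L
  for (cj in seq_len(ny - 1L)) for (ci in seq_len(nx - 1L)) {
    conn <- c(nid(ci, cj), nid(ci + 1L, cj), nid(ci + 1L, cj + 1L), nid(ci, cj + 1L))
    sl <- p + seq_len(16L)
    ii[sl] <- rep(conn, 4)
    jj[sl] <- rep(conn, each = 4)
    mm[sl] <- as.vector(Mloc)
    kk[sl] <- as.vector(Kloc)
    p <- p + 16L
  }
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = mm, dims = c(N, N))
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = kk, dims = c(N, N))
  structure(list(M = Matrix::forceSymmetric(M), K = Matrix::forceSymmetric(K),
                 n_quad = ncell * points_per_axis^2,
                 config = list(method = "fem2d", hx = hx, hy = hy, sigma = sigma,
                               points_per_axis = points_per_axis)),
            class = "efgm_system")
}
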