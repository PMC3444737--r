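#' Assemble the semi-discrete Galerkin system
#'
#' Builds the sparse mass and stiffness matrices of the weak form,
#' M_ij = int phi_i phi_j dOmega and K_ij = int grad(phi_i)^T D grad(phi_j)
#' dOmega, by looping over the background-mesh Gauss points that fall inside
#' the domain: each inside point contributes w_q phi phi^T and
#' w_q (dphi D dphi^T) over its MLS neighbourhood; outside points are
#' skipped. Constant fields produce no flux (K 1 = 0) because the shape
#' function derivatives sum to zero.
#'
#' @param cloud a [node_cloud()]
#' @param domain an `efgm_domain`
#' @param mesh a [build_background_mesh()] result
#' @param points_per_axis Gauss order per axis (1..4).
#' @param d_max influence-domain scaling.
#' @param kind weight kind (`"cubic"`/`"quartic"`).
#' @param basis `"linear"` or `"quadratic"`.
#' @param params a [diffusion_params()]
#' @param fibers optional [fiber_field()]; when given and anisotropic, the
#'   diffusion tensor is rebuilt at every quadrature point from the
#'   MLS-interpolated fiber direction.
#' @param lump_mass if `TRUE`, M is row-sum lumped to a diagonal. Default
#'   `FALSE` (consistent mass).
#' @return object of class `efgm_system`: sparse symmetric `M`, `K`, plus
#'   `radii`, `n_quad` (inside quadrature points used) and the configuration.
#' @export
assemble <- function(cloud, domain, mesh, points_per_axis = 2, d_max = 2,
                     kind = "cubic", basis = "linear",
                     params = diffusion_params(1, 1, isotropic = TRUE),
                     fibers = NULL, lump_mass = FALSE) {
  d <- cloud$dim
  N <- n_nodes(cloud)
  radii <- influence_radii(cloud, d_max)
  index <- mls_index(cloud, radii)
  qp <- gauss_points(mesh, points_per_axis, domain)
  qp <- qp[qp$inside, , drop = FALSE]
  if (nrow(qp) == 0L) stop("assemble: empty domain (no inside quadrature points)")
  pts <- as.matrix(qp[, seq_len(d), drop = FALSE])
  wq <- qp$weight
  varying_D <- !is.null(fibers) && !fibers$isotropic && !params$isotropic
  D0 <- if (!varying_D) diag(params$sigma_cf, d) else NULL
  if (!varying_D && !params$isotropic && !is.null(fibers))
    stop("assemble: anisotropic params require a fiber field")
  if (!varying_D && !is.null(fibers) && fibers$isotropic && !params$isotropic)
    D0 <- diag(params$sigma_cf, d)
  m <- basis_size(basis, d)
  acc <- triplet_accumulator(N)
  for (q in seq_len(nrow(pts))) {
    sh <- mls_shape_at(pts[q, ], cloud, radii, kind, basis, index, m, d)
    D <- if (varying_D) tensor_field(sh, fibers, params, cloud) else D0
    idx <- sh$node_indices
    Mloc <- wq[q] * tcrossprod(sh$phi)
    Kloc <- wq[q] * (sh$dphi %*% D %*% t(sh$dphi))
    acc$add(idx, Mloc, Kloc)
  }
  mats <- acc$collect()
  M <- Matrix::forceSymmetric((mats$M + Matrix::t(mats$M)) / 2)
  K <- Matrix::forceSymmetric((mats$K + Matrix::t(mats$K)) / 2)
  if (lump_mass) M <- Matrix::Diagonal(N, Matrix::rowSums(M))
  structure(list(M = M, K = K, radii = radii, n_quad = nrow(pts),
                 config = list(points_per_axis = points_per_axis, d_max = d_max,
                               kind = kind, basis = basis,
                               sigma_f = params$sigma_f,
                               sigma_cf = params$sigma_cf,
                               isotropic = params$isotropic,
                               lump_mass = lump_mass,
                               cells = mesh$cells)),
            class = "efgm_system")
}

# chunked triplet accumulator: flushes into sparse matrices to bound memory
triplet_accumulator <- function(N, flush_at = 1500000L) {
  ib <- list(); jb <- list(); mb <- list(); kb <- list()
  count <- 0L
  Msum <- NULL; Ksum <- NULL
  flush <- function() {
    if (count == 0L) return(invisible())
    i <- unlist(ib, use.names = FALSE)
    j <- unlist(jb, use.names = FALSE)
    Mn <- Matrix::sparseMatrix(i = i, j = j, x = unlist(mb, use.names = FALSE),
                               dims = c(N, N))
    Kn <- Matrix::sparseMatrix(i = i, j = j, x = unlist(kb, use.names = FALSE),
                               dims = c(N, N))
    Msum <<- if (is.null(Msum)) Mn else Msum + Mn
    Ksum <<- if (is.null(Ksum)) Kn else Ksum + Kn
    ib <<- list(); jb <<- list(); mb <<- list(); kb <<- list()
    count <<- 0L
  }
  list(
    add = function(idx, Mloc, Kloc) {
      n <- length(idx)
      k <- length(ib) + 1L
      ib[[k]] <<- rep(idx, n)
      jb[[k]] <<- rep(idx, each = n)
      mb[[k]] <<- as.vector(Mloc)
      kb[[k]] <<- as.vector(Kloc)
      count <<- count + n * n
      if (count >= flush_at) flush()
    },
    collect = function() {
      flush()
      list(M = Msum, K = Ksum)
    }
  )
}

#' @export
print.efgm_system <- function(x, ...) {
  cat(sprintf("<efgm_system> %d nodes, %d quadrature points, d_max = %g (%s weight, %s basis)\n",
              nrow(x$M), x$n_quad, x$config$d_max, x$config$kind, x$config$basis))
  invisible(x)
}

#' Dump system matrices in MatrixMarket format
#' @param sys an `efgm_system`
#' @param dir output directory (created if missing); writes `M.mtx`, `K.mtx`.
#' @export
write_system_mm <- function(sys, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(as(sys$M, "generalMatrix"), file.path(dir, "M.mtx"))
  Matrix::writeMM(as(sys$K, "generalMatrix"), file.path(dir, "K.mtx"))
  invisible(dir)
}
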