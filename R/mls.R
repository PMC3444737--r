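#' Compactly supported weight functions
#'
#' Radial weights used by the moving-least-squares approximation. Both kinds
#' are C1, positive on r < 1 and vanish for r > 1 (r is the distance
#' normalized by the influence radius):
#'
#' * `cubic`: 2/3 - 4r^2 + 4r^3 on r <= 1/2; 4/3 - 4r + 4r^2 - 4/3 r^3 on
#'   1/2 < r <= 1.
#' * `quartic`: 1 - 6r^2 + 8r^3 - 3r^4 on r <= 1.
#'
#' @param kind `"cubic"` or `"quartic"`.
#' @param r normalized distances, >= 0 (vectorized).
#' @return list with `w` and `dwdr`, same length as `r`.
#' @export
weight <- function(kind = c("cubic", "quartic"), r) {
  kind <- match.arg(kind)
  if (any(r < 0)) stop("weight: negative normalized distance")
  weight_raw(kind, r)
}

# unvalidated weight kernel used on hot paths
weight_raw <- function(kind, r) {
  w <- numeric(length(r)); dw <- numeric(length(r))
  if (kind == "cubic") {
    i1 <- r <= 0.5
    i2 <- r > 0.5 & r <= 1
    w[i1] <- 2 / 3 - 4 * r[i1]^2 + 4 * r[i1]^3
    dw[i1] <- -8 * r[i1] + 12 * r[i1]^2
    w[i2] <- 4 / 3 - 4 * r[i2] + 4 * r[i2]^2 - 4 / 3 * r[i2]^3
    dw[i2] <- -4 + 8 * r[i2] - 4 * r[i2]^2
  } else {
    i1 <- r <= 1
    w[i1] <- 1 - 6 * r[i1]^2 + 8 * r[i1]^3 - 3 * r[i1]^4
    dw[i1] <- -12 * r[i1] + 24 * r[i1]^2 - 12 * r[i1]^3
  }
  list(w = w, dwdr = dw)
}

#' Influence radii of a node cloud
#'
#' Each node I supports the approximation within radius d_mI = d_max * c_I,
#' where c_I is the node's characteristic spacing. c_I is taken as the
#' distance to the nearest other node, the simplest density-reflecting choice
#' (on a regular lattice c_I equals the grid spacing h).
#'
#' @param cloud a [node_cloud()]
#' @param d_max dimensionless scaling of the influence domain (suggested
#'   range 1 to 3; small values reproduce linear-FEM-like accuracy, larger
#'   values give smoother, more accurate approximations until oversmoothing
#'   sets in).
#' @return object of class `influence_radii` with `d_m` (per-node radius, mm),
#'   `c_I`, `d_max`.
#' @export
influence_radii <- function(cloud, d_max) {
  stopifnot(d_max > 0)
  cI <- nearest_neighbor_dist(cloud$positions)
  if (any(cI == 0)) stop("influence_radii: degenerate geometry (duplicate nodes)")
  structure(list(d_m = d_max * cI, c_I = cI, d_max = d_max),
            class = "influence_radii")
}

# nearest-neighbour distance per node via an expanding cell search
nearest_neighbor_dist <- function(pos) {
  n <- nrow(pos); d <- ncol(pos)
  if (n < 2) stop("nearest_neighbor_dist: need at least two nodes")
  lo <- apply(pos, 2, min); hi <- apply(pos, 2, max)
  ext <- pmax(hi - lo, 1e-12)
  h0 <- (prod(ext) / n)^(1 / d)
  # cap the lattice so degenerate (near-flat) clouds stay tractable
  cap <- 2L * as.integer(ceiling(n^(1 / d))) + 1L
  ncell <- pmax(1L, pmin(as.integer(ceiling(ext / h0)), cap))
  mult <- cumprod(c(1L, ncell[-d]))
  ix <- matrix(0L, n, d)
  for (k in seq_len(d))
    ix[, k] <- pmin(ncell[k] - 1L, as.integer(floor((pos[, k] - lo[k]) / (ext[k] / ncell[k]))))
  lin <- as.vector(ix %*% mult) + 1L
  bins <- vector("list", prod(ncell))
  sp <- split(seq_len(n), lin)
  bins[as.integer(names(sp))] <- sp
  ring_offsets <- function(ring) {
    o <- as.matrix(do.call(expand.grid, rep(list(-ring:ring), d)))
    if (ring > 1L) o <- o[apply(abs(o), 1, max) == ring, , drop = FALSE]
    o
  }
  off_cache <- list(ring_offsets(1L))
  cellmin <- min(ext / ncell)
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    ring <- 1L
    repeat {
      if (length(off_cache) < ring) off_cache[[ring]] <- ring_offsets(ring)
      offs <- off_cache[[ring]]
      cand <- integer(0)
      for (r in seq_len(nrow(offs))) {
        jx <- ix[i, ] + offs[r, ]
        if (any(jx < 0L) || any(jx > ncell - 1L)) next
        b <- bins[[sum(jx * mult) + 1L]]
        if (!is.null(b)) cand <- c(cand, b)
      }
      cand <- cand[cand != i]
      if (length(cand)) {
        dv <- pos[cand, , drop = FALSE] - rep(pos[i, ], each = length(cand))
        best <- min(best, sqrt(min(rowSums(dv^2))))
      }
      # all nodes within (ring-1)*cellmin of the cell are covered
      if (is.finite(best) && best <= (ring - 1L) * cellmin) break
      if (ring > max(ncell)) break
      ring <- ring + 1L
    }
    out[i] <- best
  }
  out
}

#' Spatial index for influence-domain queries
#'
#' Bins nodes on a uniform grid with cell size = max influence radius so that
#' all nodes possibly covering a point lie in the 3^d adjacent cells.
#'
#' @param cloud a [node_cloud()]
#' @param radii an [influence_radii()]
#' @return an opaque index object used by [neighbors()] and [mls_shape()].
#' @export
mls_index <- function(cloud, radii) {
  pos <- cloud$positions
  d <- ncol(pos)
  lo <- apply(pos, 2, min) - 1e-9
  hi <- apply(pos, 2, max) + 1e-9
  cs <- max(radii$d_m)
  ncell <- pmax(1L, as.integer(ceiling((hi - lo) / cs)))
  ix <- matrix(0L, nrow(pos), d)
  for (k in seq_len(d))
    ix[, k] <- pmin(ncell[k] - 1L, as.integer(floor((pos[, k] - lo[k]) / cs)))
  mult <- cumprod(c(1L, ncell[-d]))
  lin <- as.vector(ix %*% mult) + 1L
  bins <- vector("list", prod(ncell))
  sp <- split(seq_len(nrow(pos)), lin)
  bins[as.integer(names(sp))] <- sp
  offsets <- as.matrix(do.call(expand.grid, rep(list(-1:1), d)))
  # precompute linear offsets of the 3^d neighbourhood
  loff <- as.vector(offsets %*% mult)
  list(pos = pos, d_m = radii$d_m, lo = lo, cs = cs, ncell = ncell,
       mult = mult, bins = bins, offsets = offsets, loff = loff, dim = d)
}

query_index <- function(index, point) {
  ixp <- pmin(index$ncell - 1L, pmax(0L, as.integer(floor((point - index$lo) / index$cs))))
  # drop neighbour cells that fall outside the bin lattice
  ok <- rep(TRUE, nrow(index$offsets))
  for (k in seq_len(index$dim)) {
    v <- ixp[k] + index$offsets[, k]
    ok <- ok & v >= 0L & v <= index$ncell[k] - 1L
  }
  cells <- sum(ixp * index$mult) + 1L + index$loff[ok]
  unlist(index$bins[cells], use.names = FALSE)
}

#' Nodes whose influence domains cover a point
#'
#' @param point coordinates (length d).
#' @param cloud a [node_cloud()]
#' @param radii an [influence_radii()]
#' @param index optional prebuilt [mls_index()] (built on the fly otherwise).
#' @return integer vector of node indices (1-based, ascending), possibly empty.
#' @export
neighbors <- function(point, cloud, radii, index = NULL) {
  if (is.null(index)) index <- mls_index(cloud, radii)
  cand <- query_index(index, as.numeric(point))
  if (!length(cand)) return(integer(0))
  dv <- index$pos[cand, , drop = FALSE] - rep(as.numeric(point), each = length(cand))
  keep <- rowSums(dv^2) < index$d_m[cand]^2
  sort(cand[keep])
}

basis_size <- function(basis, d) {
  switch(basis, linear = d + 1L,
         quadratic = 1L + d + d * (d + 1L) / 2L,
         stop("unknown basis kind"))
}

# monomial design matrix on local coordinates y (n x d), including row for
# the evaluation point at the origin handled analytically elsewhere
basis_matrix <- function(y, basis) {
  n <- nrow(y); d <- ncol(y)
  if (basis == "linear") return(cbind(1, y))
  quad <- y^2
  cross <- switch(d,
                  NULL,
                  y[, 1] * y[, 2],
                  cbind(y[, 1] * y[, 2], y[, 1] * y[, 3], y[, 2] * y[, 3]))
  cbind(1, y, quad, cross)
}

#' Moving-least-squares shape functions and first derivatives
#'
#' At an evaluation point x, the field is approximated as a weighted least
#' squares fit of a polynomial basis over the n nodes whose influence domains
#' cover x: phi(x) = p(x)^T A^-1 B with A = P^T W P and B = P^T W. Spatial
#' derivatives follow from the product rule with
#' d(A^-1)/dx = -A^-1 (dA/dx) A^-1. The basis is evaluated in coordinates
#' shifted to the evaluation point, which conditions A and leaves the shape
#' functions unchanged (MLS commutes with translation for a complete basis).
#'
#' The resulting functions form a partition of unity and reproduce any field
#' that is a polynomial of the basis exactly.
#'
#' If fewer than m nodes are found or A is numerically singular, the search
#' radius about the point is enlarged by factors of 1.2 (at most 8 times)
#' before a singular-moment-matrix error is raised.
#'
#' @param point evaluation coordinates (length d), mm.
#' @param cloud a [node_cloud()]
#' @param radii an [influence_radii()]
#' @param kind weight kind, `"cubic"` or `"quartic"`.
#' @param basis `"linear"` or `"quadratic"`.
#' @param index optional prebuilt [mls_index()].
#' @return object of class `shape_eval`: `point`, `node_indices`, `phi`
#'   (length n), `dphi` (n x d, units 1/mm).
#' @export
mls_shape <- function(point, cloud, radii, kind = c("cubic", "quartic"),
                      basis = c("linear", "quadratic"), index = NULL) {
  kind <- match.arg(kind)
  basis <- match.arg(basis)
  point <- as.numeric(point)
  d <- cloud$dim
  m <- basis_size(basis, d)
  if (is.null(index)) index <- mls_index(cloud, radii)
  idx <- neighbors(point, cloud, radii, index)
  scale <- 1
  for (attempt in 0:8) {
    if (attempt > 0) {
      scale <- scale * 1.2
      dv <- cloud$positions - rep(point, each = nrow(cloud$positions))
      idx <- which(rowSums(dv^2) < (scale * radii$d_m)^2)
    }
    if (length(idx) < m) next
    res <- mls_eval(point, cloud$positions[idx, , drop = FALSE],
                    radii$d_m[idx] * scale, kind, basis, m, d)
    if (!is.null(res)) {
      return(structure(list(point = point, node_indices = idx,
                            phi = res$phi, dphi = res$dphi),
                       class = "shape_eval"))
    }
  }
  stop(sprintf(
    "mls_shape: singular moment matrix at point (%s) with %d neighbours (need >= %d well-placed nodes)",
    paste(signif(point, 6), collapse = ", "), length(idx), m))
}

# fast internal entry point used by assembly: skips argument matching and
# neighbour sorting (summation order does not affect the assembled matrices);
# falls back to the robust enlarging path on failure
mls_shape_at <- function(point, cloud, radii, kind, basis, index, m, d) {
  cand <- query_index(index, point)
  if (length(cand) >= m) {
    dv <- index$pos[cand, , drop = FALSE] - rep(point, each = length(cand))
    idx <- cand[rowSums(dv^2) < index$d_m[cand]^2]
    if (length(idx) >= m) {
      res <- mls_eval(point, cloud$positions[idx, , drop = FALSE],
                      radii$d_m[idx], kind, basis, m, d)
      if (!is.null(res))
        return(list(point = point, node_indices = idx,
                    phi = res$phi, dphi = res$dphi))
    }
  }
  sh <- mls_shape(point, cloud, radii, kind, basis, index)
  list(point = sh$point, node_indices = sh$node_indices,
       phi = sh$phi, dphi = sh$dphi)
}

# core evaluation; returns NULL if the moment matrix is not SPD or is too
# ill-conditioned to trust (nearly coplanar/collinear neighbourhoods near a
# curved boundary) - the caller then enlarges the search radius.
mls_eval <- function(point, xs, dm, kind, basis, m, d, cond_limit = 1e4) {
  y <- xs - rep(point, each = nrow(xs))          # local coordinates
  dist <- sqrt(rowSums(y^2))
  r <- dist / dm
  wg <- weight_raw(kind, r)
  w <- wg$w
  if (sum(w > 0) < m) return(NULL)
  # d r / d point_i = -y_i / (dist * dm); zero where the point sits on a node
  inv <- numeric(length(dist))
  posd <- dist > 0
  inv[posd] <- 1 / (dist[posd] * dm[posd])
  # basis on radius-normalized coordinates: A becomes scale-free, so its
  # condition number measures neighbourhood geometry, not units
  s <- max(dm)
  P <- basis_matrix(y / s, basis)
  A <- crossprod(P, P * w)
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  dc <- diag(ch)
  if ((max(dc) / min(dc))^2 > cond_limit) return(NULL)
  solve_chol <- function(rhs) backsolve(ch, backsolve(ch, rhs, transpose = TRUE))
  Z <- solve_chol(t(P * w))                      # A^-1 B, m x n
  E <- diag(m)[, seq_len(d + 1L), drop = FALSE]
  E[, -1L] <- E[, -1L] / s                       # grad p(0) picks up the 1/s scale
  G <- solve_chol(E)                             # A^-1 [p0, grad p0]
  gam <- G[, 1L]
  phi <- Z[1L, ]
  a <- drop(P %*% gam)
  dphi <- matrix(0, length(w), d)
  for (i in seq_len(d)) {
    dwi <- wg$dwdr * (-y[, i]) * inv
    u <- drop(crossprod(P, a * dwi))             # gamma^T dA/dx_i  (length m)
    dphi[, i] <- drop(P %*% G[, i + 1L]) * w + a * dwi - drop(crossprod(Z, u))
  }
  list(phi = phi, dphi = dphi)
}

#' @export
print.shape_eval <- function(x, ...) {
  cat(sprintf("<shape_eval> at (%s): %d nodes, sum(phi) = %.12f\n",
              paste(signif(x$point, 6), collapse = ", "),
              length(x$phi), sum(x$phi)))
  invisible(x)
}
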