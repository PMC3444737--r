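# Independent oracles used across the test suite. These deliberately avoid
# the package's computational paths: the MLS oracle solves the weighted
# normal equations directly in global (unshifted) coordinates, the assembly
# oracle integrates with a dense high-order Gauss rule, and the cable oracle
# is a plain finite-difference simulation.

# polynomial basis in global coordinates
oracle_basis <- function(x, basis, d) {
  x <- matrix(x, ncol = d)
  if (basis == "linear") return(cbind(1, x))
  if (d == 1) return(cbind(1, x, x^2))
  if (d == 2) return(cbind(1, x, x^2, x[, 1] * x[, 2]))
  cbind(1, x, x^2, x[, 1] * x[, 2], x[, 1] * x[, 3], x[, 2] * x[, 3])
}

# weight kernels restated independently
oracle_weight <- function(kind, r) {
  if (kind == "cubic") {
    ifelse(r <= 0.5, 2/3 - 4*r^2 + 4*r^3,
           ifelse(r <= 1, 4/3 - 4*r + 4*r^2 - 4/3*r^3, 0))
  } else {
    ifelse(r <= 1, 1 - 6*r^2 + 8*r^3 - 3*r^4, 0)
  }
}

# shape functions as the minimizer of the weighted least-squares functional,
# computed by solving the normal equations for each nodal unit vector
oracle_mls <- function(point, positions, d_m, kind = "cubic", basis = "linear") {
  d <- ncol(positions)
  r <- sqrt(rowSums((positions - rep(point, each = nrow(positions)))^2)) / d_m
  w <- oracle_weight(kind, r)
  idx <- which(w > 0)
  P <- oracle_basis(positions[idx, , drop = FALSE], basis, d)
  A <- t(P) %*% (w[idx] * P)
  B <- t(P * w[idx])
  phi <- drop(oracle_basis(point, basis, d) %*% solve(A, B))
  list(phi = phi, idx = idx)
}

# dense assembly of M and K on a 1D bar with many Gauss points per cell
oracle_assemble_1d <- function(positions, d_m, sigma, n_cells, kind = "cubic",
                               pts_per_cell = 50) {
  n <- length(positions)
  lo <- min(positions); hi <- max(positions)
  edges <- seq(lo, hi, length.out = n_cells + 1)
  gl <- pracma::gaussLegendre(pts_per_cell, -1, 1)
  M <- matrix(0, n, n); K <- matrix(0, n, n)
  h <- 1e-7
  pos <- matrix(positions, ncol = 1)
  for (c in seq_len(n_cells)) {
    a <- edges[c]; b <- edges[c + 1]
    xq <- (a + b) / 2 + gl$x * (b - a) / 2
    wq <- gl$w * (b - a) / 2
    for (q in seq_along(xq)) {
      o <- oracle_mls(xq[q], pos, d_m, kind)
      phi <- numeric(n); phi[o$idx] <- o$phi
      op <- oracle_mls(xq[q] + h, pos, d_m, kind)
      om <- oracle_mls(xq[q] - h, pos, d_m, kind)
      pp <- numeric(n); pp[op$idx] <- op$phi
      pm <- numeric(n); pm[om$idx] <- om$phi
      dphi <- (pp - pm) / (2 * h)
      M <- M + wq[q] * tcrossprod(phi)
      K <- K + wq[q] * sigma * tcrossprod(dphi)
    }
  }
  list(M = M, K = K)
}

# fine-grid explicit finite-difference cable oracle: front speed from
# half-amplitude crossing times of two interior probes
oracle_cable_speed <- function(sigma, params = cubic_ionic_params(),
                               length_mm = 20, h = 0.01, dt = 1e-4) {
  n <- as.integer(round(length_mm / h)) + 1L
  x <- seq(0, length_mm, by = h)
  D <- sigma / (params$A_m * params$C_m)
  v <- numeric(n)
  v[x <= 1] <- params$v_p
  cross <- rep(NA_real_, n)
  vth50 <- params$v_p / 2
  t <- 0
  t_max <- length_mm / 0.2 + 20
  while (t < t_max && anyNA(cross[x >= 5 & x <= 15])) {
    lap <- c(2 * (v[2] - v[1]),
             v[1:(n - 2)] - 2 * v[2:(n - 1)] + v[3:n],
             2 * (v[n - 1] - v[n])) / h^2
    ion <- params$g * v * (1 - v / params$v_th) * (1 - v / params$v_p)
    vn <- v + dt * (D * lap - ion / params$C_m)
    newly <- which(is.na(cross) & vn >= vth50)
    if (length(newly)) {
      frac <- (vth50 - v[newly]) / (vn[newly] - v[newly])
      cross[newly] <- t + frac * dt
    }
    v <- vn
    t <- t + dt
  }
  i1 <- which.min(abs(x - 5)); i2 <- which.min(abs(x - 15))
  if (is.na(cross[i1]) || is.na(cross[i2]))
    stop("oracle_cable_speed: wave did not cross the probes")
  (x[i2] - x[i1]) / (cross[i2] - cross[i1])
}

# small deterministic irregular cloud for property tests; spacing scales
# with n to stay well below the Poisson-disk jamming density
helper_cloud_2d <- function(n = 60, seed = 11) {
  dom <- box_domain(rbind(c(0, 0), c(10, 10)))
  make_irregular_cloud(dom, n, min_spacing = min(0.7, 7 / sqrt(n)), seed = seed)
}
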