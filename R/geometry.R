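#' Meshfree particle representations of cardiac and test geometries
#'
#' A *node cloud* is the meshfree counterpart of a mesh: a set of unstructured
#' sample nodes with no predefined connectivity. Field variables (potential,
#' fiber orientation) live on the nodes and are approximated in between by the
#' moving-least-squares shape functions of [mls_shape()].
#'
#' @name geometry
#' @keywords internal
NULL

#' Construct a node cloud
#'
#' @param positions numeric matrix (N x d), coordinates in mm, d in 1:3.
#'   A numeric vector is taken as 1D coordinates.
#' @return An object of class `node_cloud` with elements `positions` (N x d
#'   matrix), `ids` (0-based integer labels) and `dim`.
#' @export
node_cloud <- function(positions) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 1L)
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  dimnames(positions) <- NULL
  d <- ncol(positions)
  if (!d %in% 1:3) stop("node_cloud: dimension must be 1, 2 or 3")
  if (!all(is.finite(positions))) stop("node_cloud: non-finite coordinates")
  if (anyDuplicated(positions)) stop("node_cloud: coincident nodes")
  structure(
    list(positions = positions, ids = seq_len(nrow(positions)) - 1L, dim = d),
    class = "node_cloud"
  )
}

#' @export
print.node_cloud <- function(x, ...) {
  cat(sprintf("<node_cloud> %d nodes in %dD\n", nrow(x$positions), x$dim))
  bb <- apply(x$positions, 2, range)
  cat("  bounding box:",
      paste(sprintf("[%.3g, %.3g]", bb[1, ], bb[2, ]), collapse = " x "),
      "mm\n")
  invisible(x)
}

#' Number of nodes in a cloud
#' @param cloud a [node_cloud()]
#' @return integer node count
#' @export
n_nodes <- function(cloud) nrow(cloud$positions)

#' Define a computational domain
#'
#' A domain is an `inside` predicate plus an axis-aligned bounding box. The
#' background mesh tiles the bounding box; quadrature points are kept only
#' where `inside` is `TRUE` (partially covered cells contribute the weights of
#' their interior Gauss points, the rest are ignored).
#'
#' @param inside function taking an N x d coordinate matrix, returning a
#'   logical vector.
#' @param bbox 2 x d matrix, rows = (lower, upper) bounds in mm.
#' @param name descriptive label.
#' @return object of class `efgm_domain`.
#' @export
make_domain <- function(inside, bbox, name = "domain") {
  bbox <- as.matrix(bbox)
  if (nrow(bbox) != 2L || any(bbox[2, ] <= bbox[1, ]))
    stop("make_domain: bbox must be a 2 x d matrix with upper > lower")
  structure(list(inside = inside, bbox = bbox, name = name),
            class = "efgm_domain")
}

#' @export
print.efgm_domain <- function(x, ...) {
  cat(sprintf("<efgm_domain> '%s', bbox %s mm\n", x$name,
              paste(sprintf("[%.3g, %.3g]", x$bbox[1, ], x$bbox[2, ]),
                    collapse = " x ")))
  invisible(x)
}

#' Axis-aligned box domain
#' @param bounds 2 x d matrix or length-2 vector (1D), mm.
#' @param name label.
#' @return an `efgm_domain`
#' @export
box_domain <- function(bounds, name = "box") {
  if (is.null(dim(bounds))) bounds <- matrix(bounds, ncol = 1L)
  bounds <- as.matrix(bounds)
  lo <- bounds[1, ]; hi <- bounds[2, ]
  tol <- 1e-9 * max(hi - lo)
  make_domain(
    inside = function(p) {
      p <- coerce_points(p, length(lo))
      ok <- rep(TRUE, nrow(p))
      for (k in seq_along(lo))
        ok <- ok & p[, k] >= lo[k] - tol & p[, k] <= hi[k] + tol
      ok
    },
    bbox = bounds, name = name
  )
}

coerce_points <- function(p, d) {
  if (is.null(dim(p))) {
    if (d == 1L) p <- matrix(p, ncol = 1L) else p <- matrix(p, ncol = d, byrow = TRUE)
  }
  as.matrix(p)
}

#' Regular tensor-product node lattice
#'
#' @param bounds per-axis interval, 2 x d matrix (or length-2 vector in 1D), mm.
#' @param counts per-axis node counts (>= 2 each).
#' @return list with `cloud` ([node_cloud()]) and `domain` (the bounding box).
#' @examples
#' g <- make_regular_grid(c(0, 20), 21)       # 1D, spacing 1 mm
#' g2 <- make_regular_grid(rbind(c(0, 0), c(20, 20)), c(21, 21))
#' @export
make_regular_grid <- function(bounds, counts) {
  if (is.null(dim(bounds))) bounds <- matrix(bounds, ncol = 1L)
  bounds <- as.matrix(bounds)
  d <- ncol(bounds)
  counts <- as.integer(counts)
  if (length(counts) == 1L) counts <- rep(counts, d)
  if (length(counts) != d) stop("make_regular_grid: counts/bounds mismatch")
  if (any(counts < 2L)) stop("make_regular_grid: counts must be >= 2 per axis")
  if (any(bounds[2, ] <= bounds[1, ])) stop("make_regular_grid: degenerate bounds")
  axes <- lapply(seq_len(d), function(k)
    seq(bounds[1, k], bounds[2, k], length.out = counts[k]))
  pos <- as.matrix(do.call(expand.grid, axes))
  colnames(pos) <- NULL
  list(cloud = node_cloud(pos),
       domain = box_domain(bounds, name = paste0("grid-", paste(counts, collapse = "x"))))
}

#' Irregular node cloud by Poisson-disk-style dart throwing
#'
#' Draws uniform candidate points in the domain bounding box, keeps those that
#' are inside the domain and at least `min_spacing` away from every accepted
#' node (checked through a cell-binned spatial index), until `n` nodes are
#' placed. Deterministic for a given `seed`.
#'
#' @param domain an `efgm_domain`.
#' @param n number of nodes to place.
#' @param min_spacing minimum pairwise distance, mm.
#' @param seed integer RNG seed.
#' @param max_tries retry cap; default `1000 * n` attempts.
#' @return a [node_cloud()]
#' @export
make_irregular_cloud <- function(domain, n, min_spacing, seed,
                                 max_tries = 1000L * n) {
  stopifnot(n >= 1L, min_spacing > 0)
  lo <- domain$bbox[1, ]; hi <- domain$bbox[2, ]
  d <- length(lo)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  # cell list with cell size = min_spacing: neighbours live in adjacent cells
  ncell <- pmax(1L, as.integer(floor((hi - lo) / min_spacing)))
  cellsz <- (hi - lo) / ncell
  bins <- new.env(hash = TRUE, parent = emptyenv())
  key <- function(ix) paste(ix, collapse = ",")
  accepted <- matrix(0, n, d)
  placed <- 0L
  tries <- 0L
  batch <- max(256L, 4L * n)
  while (placed < n && tries < max_tries) {
    m <- min(batch, max_tries - tries)
    cand <- matrix(stats::runif(m * d, rep(lo, each = m), rep(hi, each = m)), m, d)
    tries <- tries + m
    keep <- domain$inside(cand)
    for (i in which(keep)) {
      p <- cand[i, ]
      ix <- pmin(ncell - 1L, as.integer(floor((p - lo) / cellsz)))
      ok <- TRUE
      nb <- as.matrix(do.call(expand.grid, rep(list(-1:1), d)))
      for (r in seq_len(nrow(nb))) {
        jx <- ix + nb[r, ]
        if (any(jx < 0L) || any(jx > ncell - 1L)) next
        ids <- bins[[key(jx)]]
        if (is.null(ids)) next
        dv <- accepted[ids, , drop = FALSE] - rep(p, each = length(ids))
        if (any(rowSums(dv^2) < min_spacing^2)) { ok <- FALSE; break }
      }
      if (ok) {
        placed <- placed + 1L
        accepted[placed, ] <- p
        k <- key(ix)
        bins[[k]] <- c(bins[[k]], placed)
        if (placed == n) break
      }
    }
  }
  if (placed < n)
    stop(sprintf(
      "make_irregular_cloud: capacity error, placed %d of %d nodes after %d tries (min_spacing likely infeasible)",
      placed, n, tries))
  node_cloud(accepted[seq_len(n), , drop = FALSE])
}

#' Fiber field attached to a node cloud
#'
#' @param vectors N x 3 (or N x 2) matrix of unit fiber vectors, or `NULL` for
#'   an isotropic field.
#' @param isotropic logical flag.
#' @return object of class `fiber_field` with `vectors`, `isotropic`.
#' @export
fiber_field <- function(vectors = NULL, isotropic = is.null(vectors)) {
  if (!isotropic) {
    vectors <- as.matrix(vectors)
    dimnames(vectors) <- NULL
    nrm <- sqrt(rowSums(vectors^2))
    if (any(abs(nrm - 1) > 1e-12))
      stop("fiber_field: vectors must be unit length")
  }
  structure(list(vectors = vectors, isotropic = isotropic),
            class = "fiber_field")
}

#' @export
print.fiber_field <- function(x, ...) {
  if (x$isotropic) cat("<fiber_field> isotropic\n")
  else cat(sprintf("<fiber_field> %d unit fiber vectors\n", nrow(x$vectors)))
  invisible(x)
}

#' Uniform fiber field
#'
#' Every node carries the same (normalized) direction, e.g. the
#' (0.57735, 0.57735, -0.57735) scenario of the cube plane-wave experiment.
#'
#' @param cloud a [node_cloud()]
#' @param direction nonzero vector; stored normalized.
#' @return a [fiber_field()]
#' @export
assign_uniform_fibers <- function(cloud, direction) {
  direction <- as.numeric(direction)
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("assign_uniform_fibers: zero direction vector")
  u <- direction / nrm
  fiber_field(matrix(u, n_nodes(cloud), length(u), byrow = TRUE))
}

#' Two-region fiber field split by a plane
#'
#' Nodes on the negative side of the plane `x . normal < offset` get `dir_a`,
#' the rest `dir_b` (the "half and half" cube scenario).
#'
#' @param cloud a [node_cloud()]
#' @param normal plane normal.
#' @param offset plane offset along the normal (mm).
#' @param dir_a,dir_b nonzero direction vectors for each side.
#' @return a [fiber_field()]
#' @export
assign_split_fibers <- function(cloud, normal, offset, dir_a, dir_b) {
  norm2 <- function(v) { n <- sqrt(sum(v^2)); if (n == 0) stop("zero direction"); v / n }
  a <- norm2(as.numeric(dir_a)); b <- norm2(as.numeric(dir_b))
  side <- drop(cloud$positions %*% as.numeric(normal)) < offset
  vec <- matrix(b, n_nodes(cloud), length(b), byrow = TRUE)
  vec[side, ] <- matrix(a, sum(side), length(a), byrow = TRUE)
  fiber_field(vec)
}

#' Idealized ventricular shell with rule-based fibers (synthetic)
#'
#' Generates a synthetic stand-in for an anatomical ventricular geometry: a
#' truncated prolate ellipsoidal shell filled with a Poisson-disk node cloud.
#' The fiber at each node lies in the local circumferential-longitudinal plane
#' with a helix angle interpolated linearly through the wall from the
#' endocardial to the epicardial value (default +60 deg to -60 deg), the
#' canonical idealized-LV convention.
#'
#' @param epi_axes,endo_axes semi-axes (a, b, c) of the outer and inner
#'   ellipsoid, mm; `endo_axes` must be strictly inside `epi_axes`.
#' @param base_z truncation height: the shell keeps z <= `base_z` (apex at
#'   z = -c_epi).
#' @param n target node count.
#' @param helix_range length-2 vector, helix angle in degrees at (endo, epi).
#' @param seed RNG seed for node placement.
#' @param min_spacing node spacing; default scales with shell volume / n.
#' @return list with `cloud`, `fibers`, `domain`, and `transmural` (per-node
#'   normalized wall depth, 0 = endo, 1 = epi).
#' @export
make_ventricle_shell <- function(epi_axes = c(35, 35, 50),
                                 endo_axes = c(24, 24, 40),
                                 base_z = 15, n = 3164,
                                 helix_range = c(60, -60),
                                 seed = 1, min_spacing = NULL) {
  if (any(endo_axes >= epi_axes))
    stop("make_ventricle_shell: endo semi-axes must lie strictly inside epi semi-axes")
  g <- function(p, ax) (p[, 1] / ax[1])^2 + (p[, 2] / ax[2])^2 + (p[, 3] / ax[3])^2
  inside <- function(p) {
    p <- coerce_points(p, 3L)
    g(p, epi_axes) <= 1 & g(p, endo_axes) >= 1 & p[, 3] <= base_z
  }
  bbox <- rbind(c(-epi_axes[1], -epi_axes[2], -epi_axes[3]),
                c(epi_axes[1], epi_axes[2], base_z))
  dom <- make_domain(inside, bbox, name = "ventricle-shell")
  if (is.null(min_spacing)) {
    # crude shell volume estimate for a feasible Poisson-disk radius
    vol <- 4 / 3 * pi * (prod(epi_axes) - prod(endo_axes)) * 0.6
    min_spacing <- 0.72 * (vol / n)^(1 / 3)
  }
  cloud <- make_irregular_cloud(dom, n, min_spacing, seed)
  tf <- ventricle_fibers(cloud, epi_axes, endo_axes, helix_range)
  list(cloud = cloud, fibers = tf$fibers, domain = dom,
       transmural = tf$transmural)
}

# Rule-based fibers on an ellipsoidal shell: transmural coordinate t solves
# g(x; axes(t)) = 1 on the linearly interpolated ellipsoid family, then the
# helix angle is linear in t and the fiber is rotated within the local
# circumferential-longitudinal plane.
ventricle_fibers <- function(cloud, epi_axes, endo_axes, helix_range) {
  p <- cloud$positions
  nn <- nrow(p)
  tmural <- numeric(nn)
  fib <- matrix(0, nn, 3)
  for (i in seq_len(nn)) {
    x <- p[i, ]
    f <- function(t) {
      ax <- endo_axes + t * (epi_axes - endo_axes)
      sum((x / ax)^2) - 1
    }
    t <- if (f(0) <= 0) 0 else if (f(1) >= 0) 1 else stats::uniroot(f, c(0, 1))$root
    tmural[i] <- t
    ax <- endo_axes + t * (epi_axes - endo_axes)
    nrml <- 2 * x / ax^2                      # outward transmural normal
    nrml <- nrml / sqrt(sum(nrml^2))
    circ <- c(-nrml[2], nrml[1], 0)           # z-hat x normal
    cn <- sqrt(sum(circ^2))
    if (cn < 1e-8) circ <- c(1, 0, 0) else circ <- circ / cn  # apex fallback
    long <- c(nrml[2] * circ[3] - nrml[3] * circ[2],
              nrml[3] * circ[1] - nrml[1] * circ[3],
              nrml[1] * circ[2] - nrml[2] * circ[1])
    long <- long / sqrt(sum(long^2))
    ang <- (helix_range[1] + t * (helix_range[2] - helix_range[1])) * pi / 180
    v <- cos(ang) * circ + sin(ang) * long
    fib[i, ] <- v / sqrt(sum(v^2))
  }
  list(fibers = fiber_field(fib), transmural = tmural)
}

#' Read / write the plain-text node + fiber table
#'
#' Format: whitespace-separated, header `id x y z [fx fy fz]`, 0-based ids,
#' coordinates in mm. Lower-dimensional clouds use fewer coordinate columns.
#'
#' @param path file path.
#' @return `read_node_file`: list with `cloud` and `fibers` (NULL if the file
#'   carries no fiber columns).
#' @export
read_node_file <- function(path) {
  tab <- utils::read.table(path, header = TRUE)
  cn <- names(tab)
  coord <- intersect(c("x", "y", "z"), cn)
  cloud <- node_cloud(as.matrix(tab[, coord, drop = FALSE]))
  fibers <- NULL
  fcols <- intersect(c("fx", "fy", "fz"), cn)
  if (length(fcols) > 0) {
    v <- as.matrix(tab[, fcols, drop = FALSE])
    v <- v / sqrt(rowSums(v^2))
    fibers <- fiber_field(v)
  }
  list(cloud = cloud, fibers = fibers)
}

#' @rdname read_node_file
#' @param cloud a [node_cloud()]
#' @param fibers optional [fiber_field()]
#' @export
write_node_file <- function(cloud, path, fibers = NULL) {
  d <- cloud$dim
  tab <- data.frame(id = cloud$ids)
  cn <- c("x", "y", "z")[seq_len(d)]
  for (k in seq_len(d)) tab[[cn[k]]] <- cloud$positions[, k]
  if (!is.null(fibers) && !fibers$isotropic) {
    fn <- c("fx", "fy", "fz")[seq_len(ncol(fibers$vectors))]
    for (k in seq_along(fn)) tab[[fn[k]]] <- fibers$vectors[, k]
  }
  utils::write.table(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
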