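test_that("weight kernels match their printed branches and support", {
  w <- weight("cubic", c(0, 0.5, 1.2))
  expect_equal(w$w, c(2 / 3, 1 / 6, 0))
  expect_equal(w$dwdr[3], 0)
  wq <- weight("quartic", c(0, 1, 2))
  expect_equal(wq$w, c(1, 0, 0))
  expect_error(weight("cubic", -0.1), "negative")
})

test_that("weights are C1 across their branch points", {
  eps <- 1e-8
  for (kind in c("cubic", "quartic")) {
    for (r0 in c(0.5, 1)) {
      lo <- weight(kind, r0 - eps)
      hi <- weight(kind, r0 + eps)
      slope <- max(abs(weight(kind, seq(0, 1, 0.01))$dwdr))
      expect_lte(abs(lo$w - hi$w), 3 * eps * slope)
      expect_lte(abs(lo$dwdr - hi$dwdr), 1e-6)
    }
  }
})

test_that("influence radii scale the nearest-neighbour spacing", {
  g <- make_regular_grid(rbind(c(0, 0), c(4, 4)), c(5, 5))  # h = 1
  r <- influence_radii(g$cloud, 2.0)
  expect_equal(r$d_m, rep(2, 25))

  two <- node_cloud(matrix(c(0, 3), ncol = 1))
  r2 <- influence_radii(two, 1.5)
  expect_equal(r2$d_m, c(4.5, 4.5))

  r11 <- influence_radii(g$cloud, 1.1)
  expect_equal(r11$d_m, 1.1 * r11$c_I)
  expect_error(node_cloud(matrix(c(0, 0, 1, 0, 0, 1), 3, 2, byrow = TRUE)[c(1, 1, 2), ]),
               "coincident")
})

test_that("neighbour queries return exactly the covering influence domains", {
  g <- make_regular_grid(c(0, 10), 11)          # 1D, h = 1
  r <- influence_radii(g$cloud, 2.0)
  idx <- mls_index(g$cloud, r)
  # point at node 5 (x = 5): nodes within strict distance 2 -> x in {4,5,6}
  nb <- neighbors(5, g$cloud, r, idx)
  expect_identical(nb, 5:7)                     # 1-based indices of x = 4,5,6
  expect_identical(neighbors(100, g$cloud, r, idx), integer(0))
  # self-inclusion at any node
  for (k in c(1, 6, 11))
    expect_true(k %in% neighbors(g$cloud$positions[k, ], g$cloud, r, idx))
})

test_that("shape functions are a partition of unity and reproduce fields", {
  cl <- helper_cloud_2d()
  r <- influence_radii(cl, 2.5)
  idx <- mls_index(cl, r)
  set.seed(21)
  pts <- cbind(runif(300, 1, 9), runif(300, 1, 9))
  for (k in seq_len(nrow(pts))) {
    sh <- mls_shape(pts[k, ], cl, r, "cubic", "linear", idx)
    expect_lt(abs(sum(sh$phi) - 1), 1e-10)
    expect_lt(max(abs(colSums(sh$dphi))), 1e-8)
    rec <- drop(sh$phi %*% cl$positions[sh$node_indices, ])
    expect_lt(max(abs(rec - pts[k, ])), 1e-9)
    expect_gte(length(sh$phi), 3)
  }
})

test_that("a symmetric 1D configuration is symmetric and oracle-exact at the node", {
  # MLS is non-interpolatory (phi_i(x_j) != delta_ij): at the middle of
  # {0,1,2} the fit is a weighted average, symmetric in the outer nodes and
  # identical to the direct weighted-least-squares minimizer
  cl <- node_cloud(matrix(c(0, 1, 2), ncol = 1))
  r <- influence_radii(cl, 1.5)
  for (kind in c("cubic", "quartic")) {
    sh <- mls_shape(1, cl, r, kind, "linear")
    phi <- numeric(3); phi[sh$node_indices] <- sh$phi
    expect_equal(phi[1], phi[3], tolerance = 1e-12)
    expect_equal(sum(phi), 1, tolerance = 1e-12)
    expect_gt(phi[2], phi[1])
    orc <- oracle_mls(1, cl$positions, r$d_m, kind, "linear")
    of <- numeric(3); of[orc$idx] <- orc$phi
    expect_equal(phi, of, tolerance = 1e-10)
  }
})

test_that("closed-form shape functions equal the weighted least-squares oracle", {
  set.seed(33)
  for (rep in 1:30) {
    n <- sample(8:15, 1)
    pos <- matrix(runif(2 * n, 0, 4), n, 2)
    while (min(dist(pos)) < 0.15) pos <- matrix(runif(2 * n, 0, 4), n, 2)
    cl <- node_cloud(pos)
    r <- influence_radii(cl, 3.0)
    p <- runif(2, 1.2, 2.8)
    kind <- sample(c("cubic", "quartic"), 1)
    sh <- tryCatch(mls_shape(p, cl, r, kind, "linear"), error = function(e) NULL)
    if (is.null(sh)) next
    orc <- tryCatch(oracle_mls(p, pos, r$d_m, kind, "linear"),
                    error = function(e) NULL)
    if (is.null(orc)) next
    phi_full <- numeric(n); phi_full[sh$node_indices] <- sh$phi
    orc_full <- numeric(n); orc_full[orc$idx] <- orc$phi
    expect_lt(max(abs(phi_full - orc_full)), 1e-9)
  }
})

test_that("shape derivatives match central finite differences", {
  cl <- helper_cloud_2d()
  r <- influence_radii(cl, 2.2)
  idx <- mls_index(cl, r)
  set.seed(8)
  pts <- cbind(runif(20, 2, 8), runif(20, 2, 8))
  h <- 1e-6 * min(r$c_I)
  full <- function(q, kind) {
    s <- mls_shape(q, cl, r, kind, "linear", idx)
    u <- numeric(n_nodes(cl)); u[s$node_indices] <- s$phi; u
  }
  for (k in seq_len(nrow(pts))) {
    kind <- if (k %% 2) "cubic" else "quartic"
    sh <- mls_shape(pts[k, ], cl, r, kind, "linear", idx)
    for (i in 1:2) {
      ep <- pts[k, ]; ep[i] <- ep[i] + h
      em <- pts[k, ]; em[i] <- em[i] - h
      fd <- (full(ep, kind) - full(em, kind)) / (2 * h)
      an <- numeric(n_nodes(cl)); an[sh$node_indices] <- sh$dphi[, i]
      expect_lt(max(abs(fd - an)) / max(abs(an)), 1e-5)
    }
  }
})

test_that("quadratic basis reproduces quadratic fields", {
  g <- make_regular_grid(rbind(c(0, 0), c(6, 6)), c(7, 7))
  r <- influence_radii(g$cloud, 2.5)
  idx <- mls_index(g$cloud, r)
  pos <- g$cloud$positions
  u <- pos[, 1]^2 + 2 * pos[, 1] * pos[, 2] - pos[, 2]^2
  set.seed(4)
  for (k in 1:20) {
    p <- runif(2, 1, 5)
    sh <- mls_shape(p, g$cloud, r, "cubic", "quadratic", idx)
    val <- drop(sh$phi %*% u[sh$node_indices])
    expect_lt(abs(val - (p[1]^2 + 2 * p[1] * p[2] - p[2]^2)), 1e-8)
  }
})

test_that("approximation error of a smooth field converges at order >= 2", {
  errs <- c()
  hs <- c(0.5, 0.25, 0.125)
  for (h in hs) {
    g <- make_regular_grid(c(0, 4), as.integer(4 / h) + 1)
    r <- influence_radii(g$cloud, 2.0)
    idx <- mls_index(g$cloud, r)
    u <- g$cloud$positions[, 1]^2
    xe <- seq(0.5, 3.5, length.out = 41)
    e <- max(vapply(xe, function(x) {
      sh <- mls_shape(x, g$cloud, r, "cubic", "linear", idx)
      abs(drop(sh$phi %*% u[sh$node_indices]) - x^2)
    }, numeric(1)))
    errs <- c(errs, e)
  }
  order <- stats::coef(stats::lm(log(errs) ~ log(hs)))[2]
  expect_gte(order, 2 - 0.2)
})

test_that("insufficient or degenerate neighbourhoods raise the singular error", {
  cl <- node_cloud(matrix(c(0, 1, 2, 10, 11, 12), ncol = 1))
  r <- influence_radii(cl, 1.2)
  # far from every node even after 8 radius enlargements (factor ~4.3)
  expect_error(mls_shape(60, cl, r, "cubic", "linear"), "singular moment matrix")
  # collinear 2D nodes cannot support a 2D linear basis
  col2 <- node_cloud(cbind(0:4, rep(0, 5)))
  rc <- influence_radii(col2, 2)
  expect_error(mls_shape(c(2, 0.1), col2, rc, "cubic", "linear"),
               "singular moment matrix")
})

test_that("the radius-enlargement fallback rescues sparse neighbourhoods", {
  # a point covered by only 2 influence domains at d_max = 1.05 in 2D
  g <- make_regular_grid(rbind(c(0, 0), c(4, 4)), c(5, 5))
  r <- influence_radii(g$cloud, 1.05)
  sh <- mls_shape(c(1.95, 2.5), g$cloud, r, "cubic", "linear")
  # the rescued neighbourhood is marginal, so allow roundoff amplification
  expect_lt(abs(sum(sh$phi) - 1), 1e-8)
})
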