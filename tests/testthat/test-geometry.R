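test_that("regular grids have the exact lattice structure", {
  g <- make_regular_grid(rbind(c(0, 0, 0), c(60, 60, 60)), c(10, 10, 10))
  expect_equal(n_nodes(g$cloud), 1000L)
  h <- sort(unique(g$cloud$positions[, 1]))
  expect_equal(diff(h), rep(60 / 9, 9))
  expect_true(all(g$domain$inside(g$cloud$positions)))

  g2 <- make_regular_grid(rbind(c(0, 0), c(20, 20)), c(21, 21))
  expect_equal(n_nodes(g2$cloud), 441L)
  expect_equal(diff(sort(unique(g2$cloud$positions[, 2]))), rep(1, 20))

  g1 <- make_regular_grid(c(0, 1), 2)
  expect_equal(sort(g1$cloud$positions[, 1]), c(0, 1))

  expect_error(make_regular_grid(c(0, 1), 1), "counts")
  expect_error(make_regular_grid(c(1, 1), 2), "degenerate")
})

test_that("irregular clouds respect spacing, count and determinism", {
  dom <- box_domain(rbind(c(0, 0), c(10, 10)))
  c1 <- make_irregular_cloud(dom, 50, 0.8, seed = 3)
  c2 <- make_irregular_cloud(dom, 50, 0.8, seed = 3)
  expect_equal(n_nodes(c1), 50L)
  expect_identical(c1$positions, c2$positions)
  dmat <- as.matrix(dist(c1$positions))
  diag(dmat) <- Inf
  expect_gte(min(dmat), 0.8)
  expect_true(all(dom$inside(c1$positions)))

  single <- make_irregular_cloud(dom, 1, 0.5, seed = 1)
  expect_equal(n_nodes(single), 1L)

  # infeasible density -> capacity error naming the shortfall
  expect_error(make_irregular_cloud(dom, 500, 2, seed = 1, max_tries = 20000),
               "capacity")
})

test_that("fiber fields are unit length and assigned by rule", {
  g <- make_regular_grid(rbind(c(0, 0, 0), c(60, 60, 60)), c(4, 4, 4))
  f <- assign_uniform_fibers(g$cloud, c(0.57735, 0.57735, -0.57735))
  expect_equal(sqrt(rowSums(f$vectors^2)), rep(1, 64), tolerance = 1e-12)
  expect_equal(f$vectors[10, ], c(0.57735, 0.57735, -0.57735),
               tolerance = 1e-5)

  f2 <- assign_uniform_fibers(g$cloud, c(2, 0, 0))
  expect_equal(f2$vectors[1, ], c(1, 0, 0))
  expect_error(assign_uniform_fibers(g$cloud, c(0, 0, 0)), "zero")

  fs <- assign_split_fibers(g$cloud, c(1, 0, 0), 30, c(0, 1, 0), c(0, 0, 2))
  left <- g$cloud$positions[, 1] < 30
  expect_true(all(fs$vectors[left, 2] == 1))
  expect_true(all(fs$vectors[!left, 3] == 1))
})

test_that("ventricle shell contains its nodes and follows the helix rule", {
  sh <- make_ventricle_shell(n = 400, seed = 5)
  expect_equal(n_nodes(sh$cloud), 400L)
  expect_true(all(sh$domain$inside(sh$cloud$positions)))
  expect_equal(sqrt(rowSums(sh$fibers$vectors^2)), rep(1, 400),
               tolerance = 1e-12)
  expect_true(all(sh$transmural >= 0 & sh$transmural <= 1))

  # zero helix range: all fibers circumferential (perpendicular to z and to
  # the transmural direction)
  sh0 <- make_ventricle_shell(n = 200, seed = 5, helix_range = c(0, 0))
  expect_lt(max(abs(sh0$fibers$vectors[, 3])), 0.2)  # near-equatorial z-component
  expect_error(make_ventricle_shell(endo_axes = c(40, 40, 60)), "strictly inside")
})

test_that("node files round-trip through the text format", {
  g <- make_regular_grid(rbind(c(0, 0, 0), c(10, 10, 10)), c(3, 3, 3))
  f <- assign_uniform_fibers(g$cloud, c(1, 1, 0))
  path <- tempfile(fileext = ".txt")
  write_node_file(g$cloud, path, f)
  back <- read_node_file(path)
  expect_equal(back$cloud$positions, g$cloud$positions, tolerance = 1e-12)
  expect_equal(back$fibers$vectors, f$vectors, tolerance = 1e-12)
  header <- readLines(path, n = 1)
  expect_match(header, "^id x y z fx fy fz$")
})

test_that("domains validate their bounding boxes", {
  expect_error(make_domain(function(p) TRUE, rbind(c(0, 0), c(0, 1))), "bbox")
  d <- box_domain(rbind(c(0, 0), c(2, 1)))
  expect_true(d$inside(matrix(c(1, 0.5), 1)))
  expect_false(d$inside(matrix(c(3, 0.5), 1)))
})
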