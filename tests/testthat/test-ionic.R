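test_that("the cubic current has its three roots and sign structure", {
  p <- cubic_ionic_params()
  expect_equal(cubic_current(c(0, p$v_th, p$v_p), p), c(0, 0, 0))
  expect_equal(cubic_current(50, p), -0.4)   # g*50*(1-5)*(1-0.5)
  set.seed(2)
  for (k in 1:20) {
    q <- cubic_ionic_params(g = runif(1, 1e-3, 1e-2), v_th = runif(1, 5, 20),
                            v_p = runif(1, 60, 150))
    below <- runif(5, 1e-3, q$v_th * 0.999)
    above <- runif(5, q$v_th * 1.001, q$v_p * 0.999)
    expect_true(all(cubic_current(below, q) > 0))
    expect_true(all(cubic_current(above, q) < 0))
  }
  expect_error(cubic_ionic_params(v_th = 20, v_p = 10), "v_th < v_p")
})

test_that("the closed-form conduction velocity behaves like the bistable front", {
  p <- cubic_ionic_params()
  g05 <- analytic_velocity(p, 0.5)
  expect_equal(g05, 0.5656854, tolerance = 1e-6)
  # exact sqrt(sigma) scaling
  expect_equal(analytic_velocity(p, 0.25) / g05, 1 / sqrt(2), tolerance = 1e-12)
  # no front at the formula's boundary
  expect_error(analytic_velocity(cubic_ionic_params(v_th = 50, v_p = 100), 0.5),
               "no propagating front")
  # algebraically identical traveling-wave form sqrt(2 g sigma /
  # (A_m C_m^2 v_th v_p)) * (v_p/2 - v_th)
  alt <- sqrt(2 * p$g * 0.5 / (p$A_m * p$C_m^2 * p$v_th * p$v_p)) *
    (p$v_p / 2 - p$v_th)
  expect_equal(g05, alt, tolerance = 1e-14)
})

test_that("FHN reaction has the printed equilibria and rates", {
  p <- fhn_params()
  expect_equal(unlist(fhn_rhs(0, 0, p)), c(dv = 0, di = 0))
  expect_equal(fhn_rhs(p$a, 0, p)$dv, 0)
  r1 <- fhn_rhs(1, 0, p)
  expect_equal(r1$dv, 0)
  expect_equal(r1$di, 0.013)
  # defaults carry the published parameter set
  expect_equal(unlist(p[c("a", "b", "c1", "c2", "d", "sigma_f", "sigma_cf")]),
               c(a = 0.13, b = 0.013, c1 = 0.26, c2 = 0.1, d = 1, sigma_f = 4,
                 sigma_cf = 1))
})

test_that("a single FHN cell fires one action potential and recovers", {
  skip_if_not_installed("deSolve")
  p <- fhn_params()
  ref <- deSolve::ode(c(v = 0.5, i = 0), seq(0, 400, 1),
                      function(t, y, parms) {
                        r <- fhn_rhs(y[1], y[2], p)
                        list(c(r$dv, r$di))
                      }, NULL, method = "lsoda", rtol = 1e-10, atol = 1e-12)
  expect_gt(max(ref[, "v"]), 0.85)           # upstroke toward the excited branch
  expect_lt(tail(ref[, "v"], 1), 0.01)       # recovery to rest
  # no re-excitation: v is below threshold for the entire final quarter
  expect_true(all(ref[ref[, "time"] > 300, "v"] < p$a))

  # the package integrator matches the tight-tolerance reference
  sys0 <- list(M = Matrix::Diagonal(1), K = Matrix::Diagonal(1, 0))
  rhs <- make_rhs(sys0, "fhn", p)
  tr <- integrate_rk4_adaptive(list(v = 0.5, i = 0), c(0, 400), rhs,
                               rtol = 1e-7, atol = 1e-9)
  # compare at the integrator's own accepted times (no interpolation error)
  ref2 <- deSolve::ode(c(v = 0.5, i = 0), tr$times,
                       function(t, y, parms) {
                         r <- fhn_rhs(y[1], y[2], p)
                         list(c(r$dv, r$di))
                       }, NULL, method = "lsoda", rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(tr$V[, 1] - ref2[, "v"])), 1e-4)
})
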