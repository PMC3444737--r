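heat_sys_small <- local({
  g <- make_regular_grid(rbind(c(0, 0), c(4, 4)), c(9, 9))
  sys <- assemble(g$cloud, g$domain, build_background_mesh(g$domain, 8),
                  points_per_axis = 2, d_max = 2,
                  params = diffusion_params(1, 1, isotropic = TRUE))
  list(g = g, sys = sys, rhs = make_rhs(sys, "heat"))
})

test_that("forward Euler reproduces closed forms and equilibria", {
  # scalar decay dv/dt = -lambda v: one step gives v (1 - lambda dt) exactly
  sys0 <- list(M = Matrix::Diagonal(1), K = Matrix::Diagonal(1, 3))
  rhs <- make_rhs(sys0, "heat")
  st <- step_euler(list(v = 2, i = NULL), 0.1, rhs)
  expect_equal(st$v, 2 * (1 - 3 * 0.1))

  # constant field: K v = 0, state unchanged
  st2 <- step_euler(list(v = rep(1.5, 81), i = NULL), 0.01, heat_sys_small$rhs)
  expect_equal(st2$v, rep(1.5, 81), tolerance = 1e-10)

  # blow-up detection far beyond the stability bound
  expect_error(
    integrate_euler(list(v = rep(1, 81) + sin(1:81), i = NULL), 10, 400,
                    heat_sys_small$rhs),
    "blow-up")
})

test_that("diffusion conserves total mass under zero-flux conditions", {
  g <- heat_sys_small$g
  sys <- heat_sys_small$sys
  pos <- g$cloud$positions
  v0 <- exp(-((pos[, 1] - 2)^2 + (pos[, 2] - 2)^2))
  dt <- 0.5 * stable_euler_dt(sys)
  tr <- integrate_euler(list(v = v0, i = NULL), dt, 200, heat_sys_small$rhs,
                        record_every = 50)
  m0 <- sum(sys$M %*% v0)
  for (k in seq_along(tr$times)) {
    mk <- sum(sys$M %*% tr$V[k, ])
    expect_lt(abs(mk - m0) / abs(m0), 1e-6)
  }
})

test_that("Euler and adaptive RK4 agree on the heat problem", {
  sys <- heat_sys_small$sys
  pos <- heat_sys_small$g$cloud$positions
  v0 <- exp(-((pos[, 1] - 2)^2 + (pos[, 2] - 2)^2))
  dt <- stable_euler_dt(sys) / 10
  n <- ceiling(0.5 / dt)
  te <- integrate_euler(list(v = v0, i = NULL), 0.5 / n, n, heat_sys_small$rhs,
                        record_every = n)
  tr <- integrate_rk4_adaptive(list(v = v0, i = NULL), c(0, 0.5),
                               heat_sys_small$rhs, rtol = 1e-7, atol = 1e-9)
  expect_lt(max(abs(te$V[nrow(te$V), ] - tr$V[nrow(tr$V), ])), 1e-3)
})

test_that("adaptive RK4 handles trivial and stiff limits", {
  sys0 <- list(M = Matrix::Diagonal(2), K = Matrix::Diagonal(2, 0))
  rhs <- make_rhs(sys0, "heat")
  tr <- integrate_rk4_adaptive(list(v = c(1, -2), i = NULL), c(0, 5), rhs)
  expect_equal(tr$V[nrow(tr$V), ], c(1, -2))
  expect_identical(tr$stats$rejected, 0L)
  expect_lte(tr$stats$steps, 10)

  stiff <- list(M = Matrix::Diagonal(1), K = Matrix::Diagonal(1, 1e9))
  expect_error(
    integrate_rk4_adaptive(list(v = 1, i = NULL), c(0, 1),
                           make_rhs(stiff, "heat"), dt_min = 1e-6),
    "underflow")
})

test_that("activation times find the logistic inflection and flag flat traces", {
  tt <- seq(0, 20, 0.25)
  t0s <- c(8.3, 12.71)
  V <- cbind(1 / (1 + exp(-(tt - t0s[1]) / 0.7)),
             1 / (1 + exp(-(tt - t0s[2]) / 0.7)),
             rep(0.001, length(tt)))
  map <- activation_times(efgm:::sim_trace(tt, V), v_threshold = 0.5)
  expect_lt(abs(map$time[1] - t0s[1]), 0.25)
  expect_lt(abs(map$time[2] - t0s[2]), 0.25)
  expect_true(map$not_activated[3])
  # shift equivariance within a sample interval
  expect_lt(abs((map$time[2] - map$time[1]) - diff(t0s)), 0.25)
})

test_that("conduction velocity recovers exact linear fronts and the RMS form", {
  x <- seq(0, 10, 0.5)
  gam <- 0.6
  map <- structure(data.frame(time = x / gam, not_activated = FALSE),
                   class = c("activation_map", "data.frame"))
  cv <- conduction_velocity(map, matrix(x, ncol = 1), 1, 0.1, reference = gam)
  expect_equal(cv$velocity, rep(gam, length(cv$velocity)), tolerance = 1e-12)
  expect_equal(cv$rms, 0, tolerance = 1e-12)
  expect_equal(cv$mean, gam, tolerance = 1e-12)
  # printed definition: exact (1,1) vs numerical (0,2) has RMS 1
  expect_equal(rms_error(c(1, 1), c(0, 2)), 1)
  # too few activated nodes
  map2 <- structure(data.frame(time = c(1, NA, NA), not_activated = c(FALSE, TRUE, TRUE)),
                    class = c("activation_map", "data.frame"))
  expect_error(conduction_velocity(map2, matrix(1:3, ncol = 1)), "fewer than 3")
})
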