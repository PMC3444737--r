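#' Scripted verification experiments
#'
#' Four pipelines exercise the solver end to end: (i) 2D heat conduction
#' against the analytic diffusion kernel, (ii) the 1D cubic-model cable
#' against the closed-form conduction velocity, with FDM and linear-FEM
#' baselines, (iii) 3D plane waves of the FitzHugh-Nagumo model in a cube,
#' and (iv) activation of a synthetic ventricular shell.
#'
#' @name experiments
#' @keywords internal
NULL

#' 2D diffusion kernel
#'
#' Fundamental solution of C_t = sigma (C_xx + C_yy) in infinite media:
#' C = C0 / (4 pi sigma t) exp(-(x^2 + y^2) / (4 sigma t)).
#'
#' @param x,y coordinates, mm.
#' @param t time, ms.
#' @param sigma diffusivity.
#' @param C0 source strength.
#' @return kernel values.
#' @export
heat_kernel <- function(x, y, t, sigma = 1, C0 = 1) {
  C0 / (4 * pi * sigma * t) * exp(-(x^2 + y^2) / (4 * sigma * t))
}

experiment_report <- function(rows, config) {
  slope <- NA_real_
  ok <- is.finite(rows$rms) & rows$rms > 0
  if (sum(ok) >= 3 && length(unique(rows$h[ok])) >= 3) {
    fit <- stats::lm(log(rms) ~ log(h), data = rows[ok, ])
    slope <- unname(stats::coef(fit)[2])
  }
  structure(list(rows = rows, slope = slope, config = config),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>\n")
  print(x$rows, row.names = FALSE)
  if (is.finite(x$slope)) cat(sprintf("log-log slope: %.3f\n", x$slope))
  invisible(x)
}

#' 2D heat-conduction convergence experiment
#'
#' Nodes on a regular lattice over the centered square [-half, half]^2 are
#' initialized with the analytic kernel at t = 1 and integrated with forward
#' Euler to t = 2; the RMS error against the kernel at t = 2 is reported per
#' node spacing. The background mesh coincides with the node lattice
#' (optionally refined); the FEM baseline uses bilinear elements on the same
#' lattice and Gauss rule.
#'
#' @param h node spacings to sweep, mm (must divide the domain evenly).
#' @param method `"efgm"` or `"fem"`.
#' @param d_max,kind meshfree parameters (ignored for FEM).
#' @param points_per_axis Gauss order per cell.
#' @param mesh_refine background-cell refinement factor relative to the node
#'   lattice (EFGM only).
#' @param sigma diffusivity (unitless test problem).
#' @param n_steps Euler steps from t = 1 to t = 2.
#' @param half half-width of the square, mm.
#' @return an `experiment_report` with columns h, rms, method, d_max, kind.
#' @export
run_heat2d <- function(h = c(1, 0.5, 0.25), method = c("efgm", "fem"),
                       d_max = 2, kind = "cubic", points_per_axis = 4,
                       mesh_refine = 1L, sigma = 1, n_steps = 5000L,
                       half = 10) {
  method <- match.arg(method)
  rows <- data.frame()
  for (hh in h) {
    counts <- as.integer(round(2 * half / hh)) + 1L
    if (abs((counts - 1L) * hh - 2 * half) > 1e-9)
      stop(sprintf("run_heat2d: h = %g does not divide the %g x %g domain", hh, 2 * half, 2 * half))
    g <- make_regular_grid(rbind(c(-half, -half), c(half, half)), counts)
    pos <- g$cloud$positions
    if (method == "efgm") {
      mesh <- build_background_mesh(g$domain, (counts - 1L) * mesh_refine)
      sys <- assemble(g$cloud, g$domain, mesh, points_per_axis, d_max, kind,
                      params = diffusion_params(sigma, sigma, isotropic = TRUE))
    } else {
      sys <- fem2d_system(counts, counts, hh, hh, sigma, points_per_axis)
    }
    v0 <- heat_kernel(pos[, 1], pos[, 2], t = 1, sigma = sigma)
    rhs <- make_rhs(sys, "heat")
    dt <- 1 / n_steps
    dt_cap <- stable_euler_dt(sys)
    if (dt > dt_cap)
      stop(sprintf("run_heat2d: dt = %g exceeds the Euler stability bound %.3g; increase n_steps", dt, dt_cap))
    tr <- integrate_euler(list(v = v0, i = NULL), dt, n_steps, rhs, t0 = 1,
                          record_every = n_steps)
    vT <- tr$V[nrow(tr$V), ]
    rms <- rms_error(heat_kernel(pos[, 1], pos[, 2], t = 2, sigma = sigma), vT)
    rows <- rbind(rows, data.frame(h = hh, rms = rms, method = method,
                                   d_max = if (method == "efgm") d_max else NA,
                                   kind = if (method == "efgm") kind else NA))
  }
  experiment_report(rows, list(method = method, d_max = d_max, kind = kind,
                               points_per_axis = points_per_axis,
                               mesh_refine = mesh_refine, sigma = sigma,
                               n_steps = n_steps, half = half))
}

#' Euler stability bound for the diffusion operator
#'
#' Estimates the largest eigenvalue of M^-1 K by power iteration and returns
#' the step bound 1.8 / lambda_max (deterministic start vector).
#'
#' @param sys a system with `M`, `K`.
#' @param scale extra multiplier on M^-1 K in the update (e.g.
#'   1 / (A_m C_m) for the cable model).
#' @param iters power-iteration count.
#' @return step-size bound, ms.
#' @export
stable_euler_dt <- function(sys, scale = 1, iters = 50L) {
  msolve <- mass_solver(sys$M)
  n <- nrow(sys$K)
  x <- sin(seq_len(n))          # fixed, generic start vector
  lam <- 0
  for (k in seq_len(iters)) {
    y <- msolve(sys$K %*% x)
    lam <- sqrt(sum(y^2)) / sqrt(sum(x^2))
    x <- y / sqrt(sum(y^2))
  }
  1.8 / (lam * scale)
}

default_cable_rows <- function() {
  data.frame(
    method = c("fdm", "fem", "efgm", "efgm", "efgm", "efgm"),
    kind = c(NA, NA, "cubic", "cubic", "quartic", "quartic"),
    d_max = c(NA, NA, 1.5, 2.0, 1.5, 2.0),
    h = c(0.05, 0.05, 0.2, 0.8, 0.2, 0.8),
    stringsAsFactors = FALSE)
}

#' 1D cable conduction-velocity experiment
#'
#' Simulates the monodomain cable with the cubic ionic model, extracts
#' activation times (maximum upstroke) and node-wise conduction velocities,
#' and reports the mean velocity and the RMS error against the closed-form
#' speed of [analytic_velocity()]. FDM and linear-FEM baselines run on the
#' identical node sets and time stepping. Stimulus: an initial deviation of
#' v_p on the first `stim_fraction` of the fiber; velocities within
#' `trim_fraction` of either end are excluded.
#'
#' @param sigma cable conductivity, mS/mm.
#' @param rows data.frame with columns method ("fdm"/"fem"/"efgm"), kind,
#'   d_max, h; default is the standard comparison table.
#' @param fiber_length fiber length, mm (>= 20 recommended).
#' @param params a [cubic_ionic_params()]
#' @param dt Euler step, ms (capped at the stability bound).
#' @param stim_fraction initially depolarized fraction of the fiber.
#' @param trim_fraction end trim for velocity statistics.
#' @param formation_widths number of traveling-front widths (4.4 / lambda,
#'   lambda = sqrt(g v_p A_m / (2 sigma v_th))) past the stimulated region
#'   that are additionally excluded at the stimulated end: the step-like
#'   initial condition needs several widths to relax onto the traveling
#'   front, and velocities measured there reflect the stimulus, not the
#'   scheme.
#' @param points_per_axis Gauss order for the meshfree assembly.
#' @param record_dt trace recording interval, ms.
#' @return an `experiment_report`; rows gain mean_velocity, rms, gamma,
#'   failed.
#' @export
run_cable1d <- function(sigma = 0.5, rows = default_cable_rows(),
                        fiber_length = 20, params = cubic_ionic_params(),
                        dt = 0.002, stim_fraction = 0.05, trim_fraction = 0.1,
                        formation_widths = 6, points_per_axis = 4,
                        record_dt = 0.02) {
  gamma <- analytic_velocity(params, sigma)
  t_end <- fiber_length / gamma * 1.25 + 5
  # 10-90% width of the traveling front: 4.4 / lambda
  lambda <- sqrt(params$g * params$v_p * params$A_m / (2 * sigma * params$v_th))
  front_width <- 4.4 / lambda
  out <- rows
  out$mean_velocity <- NA_real_
  out$rms <- NA_real_
  out$failed <- FALSE
  for (r in seq_len(nrow(rows))) {
    hh <- rows$h[r]
    n <- as.integer(round(fiber_length / hh)) + 1L
    g <- make_regular_grid(c(0, fiber_length), n)
    sys <- switch(rows$method[r],
      fdm = fdm1d_system(n, hh, sigma),
      fem = fem1d_system(n, hh, sigma),
      efgm = {
        mesh <- build_background_mesh(g$domain, n - 1L)
        assemble(g$cloud, g$domain, mesh, points_per_axis, rows$d_max[r],
                 rows$kind[r],
                 params = diffusion_params(sigma, sigma, isotropic = TRUE))
      },
      stop("run_cable1d: unknown method ", rows$method[r]))
    amcm <- params$A_m * params$C_m
    dt_r <- min(dt, stable_euler_dt(sys, scale = 1 / amcm))
    v0 <- rep(0, n)
    v0[seq_len(max(1L, ceiling(stim_fraction * n)))] <- params$v_p
    rhs <- make_rhs(sys, "cubic_cable", params)
    n_steps <- ceiling(t_end / dt_r)
    tr <- tryCatch(
      integrate_euler(list(v = v0, i = NULL), dt_r, n_steps, rhs,
                      record_every = max(1L, round(record_dt / dt_r))),
      error = function(e) NULL)
    if (is.null(tr)) { out$failed[r] <- TRUE; next }
    map <- activation_times(tr, v_threshold = 0.5 * params$v_p)
    # initially depolarized nodes never undergo an upstroke, and the front
    # only reaches its traveling shape several widths past the stimulus:
    # both regions are excluded from the velocity statistics
    n_stim <- max(1L, ceiling(stim_fraction * n))
    margin <- g$cloud$positions[n_stim, 1] + formation_widths * front_width
    drop_idx <- which(g$cloud$positions[, 1] <= margin)
    map$time[drop_idx] <- NA_real_
    map$not_activated[drop_idx] <- TRUE
    res <- tryCatch(
      conduction_velocity(map, g$cloud$positions, 1, trim_fraction, gamma),
      error = function(e) NULL)
    if (is.null(res)) { out$failed[r] <- TRUE; next }
    out$mean_velocity[r] <- res$mean
    out$rms[r] <- res$rms
  }
  out$gamma <- gamma
  experiment_report(out, list(sigma = sigma, fiber_length = fiber_length,
                              dt = dt, stim_fraction = stim_fraction,
                              trim_fraction = trim_fraction,
                              points_per_axis = points_per_axis,
                              record_dt = record_dt, params = unclass(params)))
}

# fiber scenarios of the cube experiment
cube_fibers <- function(cloud, scenario, side) {
  va <- c(0.57735, 0.57735, -0.57735)
  vb <- c(0.57735, -0.57735, 0.57735)
  switch(scenario,
    isotropic = list(fibers = fiber_field(NULL),
                     params = diffusion_params(1, 1, isotropic = TRUE)),
    `uniform-a` = list(fibers = assign_uniform_fibers(cloud, va),
                       params = diffusion_params(4, 1)),
    `uniform-b` = list(fibers = assign_uniform_fibers(cloud, vb),
                       params = diffusion_params(4, 1)),
    split = list(fibers = assign_split_fibers(cloud, c(1, 0, 0), side / 2, va, vb),
                 params = diffusion_params(4, 1)),
    `uniform-x` = list(fibers = assign_uniform_fibers(cloud, c(1, 0, 0)),
                       params = diffusion_params(4, 1)),
    stop("unknown cube fiber scenario: ", scenario))
}

#' One FitzHugh-Nagumo plane-wave run in the cube
#'
#' Initializes v_m = 0.5 on the nodes near the stimulated face and integrates
#' the FHN monodomain system with adaptive RK4; returns the activation map
#' and the plane-wave speed along the chosen axis (from a linear fit of
#' activation time on position over the interior of the cube).
#'
#' @param cloud,domain node cloud and cube domain.
#' @param cells_per_axis background cells per axis.
#' @param scenario one of "isotropic", "uniform-a", "uniform-b", "split",
#'   "uniform-x".
#' @param points_per_axis Gauss order.
#' @param d_max,kind meshfree parameters.
#' @param fhn a [fhn_params()]
#' @param axis propagation axis (stimulated face = low end of this axis).
#' @param t_end simulation end, ms.
#' @param side cube side, mm.
#' @param rtol,atol RK4 tolerances.
#' @param snapshot_times optional snapshot times, ms.
#' @param stim_frac depth of the stimulated slab as a fraction of the side.
#'   The slab must exceed the critical nucleation width of the excitable
#'   medium, which grows with sqrt(diffusivity): the default suffices for
#'   the isotropic tensor, anisotropic runs (sigma_f = 4) need about 0.15.
#' @return list: `speed` (mm/ms), `map`, `trace`, `sys`.
#' @export
cube_wave_run <- function(cloud, domain, cells_per_axis, scenario = "isotropic",
                          points_per_axis = 2, d_max = 2, kind = "cubic",
                          fhn = fhn_params(), axis = 1, t_end = 420, side = 60,
                          rtol = 1e-5, atol = 1e-7, snapshot_times = NULL,
                          stim_frac = 0.05) {
  fib <- cube_fibers(cloud, scenario, side)
  fib$params$sigma_f <- if (fib$params$isotropic) fhn$sigma_cf else fhn$sigma_f
  fib$params$sigma_cf <- fhn$sigma_cf
  mesh <- build_background_mesh(domain, cells_per_axis)
  sys <- assemble(cloud, domain, mesh, points_per_axis, d_max, kind,
                  params = fib$params, fibers = fib$fibers)
  pos <- cloud$positions
  v0 <- rep(0, n_nodes(cloud))
  stim <- pos[, axis] <= min(pos[, axis]) + stim_frac * side
  v0[stim] <- 0.5
  rhs <- make_rhs(sys, "fhn", fhn)
  tr <- integrate_rk4_adaptive(list(v = v0, i = rep(0, length(v0))),
                               c(0, t_end), rhs, rtol, atol,
                               snapshot_times = snapshot_times)
  map <- activation_times(tr, v_threshold = 0.5)
  # stimulated nodes start depolarized: no upstroke, no activation time
  map$time[stim] <- NA_real_
  map$not_activated[stim] <- TRUE
  # propagation failure (possible on very coarse lattices): speed undefined.
  # The fit window excludes the stimulated end (where the max-dv/dt time can
  # reflect the initial diffusive transient rather than the regenerative
  # upstroke) and the far face (boundary acceleration).
  speed <- tryCatch(
    plane_wave_speed(map, pos, axis, range = c(0.2, 0.9) * side),
    error = function(e) NA_real_)
  list(speed = speed, map = map, trace = tr, sys = sys, stimulated = which(stim))
}

#' Plane-wave speed from an activation map
#'
#' Linear fit of activation time on position along the axis over the interior
#' window; speed = 1 / slope.
#'
#' @param map an [activation_times()] result.
#' @param positions node coordinates.
#' @param axis propagation axis.
#' @param range optional coordinate window used for the fit (default: all
#'   activated nodes).
#' @return speed, mm/ms.
#' @export
plane_wave_speed <- function(map, positions, axis = 1, range = NULL) {
  x <- positions[, axis]
  keep <- !map$not_activated
  if (!is.null(range)) keep <- keep & x >= range[1] & x <= range[2]
  if (sum(keep) < 3 || length(unique(x[keep])) < 2)
    stop("plane_wave_speed: fewer than 3 usable nodes on 2 distinct planes")
  fit <- stats::lm(map$time[keep] ~ x[keep])
  1 / unname(stats::coef(fit)[2])
}

#' 3D cube plane-wave experiment
#'
#' Sweeps regular node lattices in the 60 mm cube, measures the isotropic
#' FHN plane-wave speed per lattice, and declares the stabilization point:
#' the smallest lattice from which every further refinement changes the
#' speed by less than `stab_tol`.
#'
#' @param grid_counts per-axis node counts to sweep.
#' @param points_per_axis 2 or 3 Gauss points per axis.
#' @param scenario fiber scenario (see [cube_wave_run()]).
#' @param d_max,kind meshfree parameters.
#' @param fhn a [fhn_params()]
#' @param t_end simulation window, ms.
#' @param side cube side, mm.
#' @param stab_tol relative speed-change threshold for stabilization.
#' @return an `experiment_report` (rows: n_per_axis, speed) with
#'   `stabilization` (node count per axis, NA if never stable).
#' @export
run_cube3d <- function(grid_counts = 3:12, points_per_axis = 2,
                       scenario = "isotropic", d_max = 2, kind = "cubic",
                       fhn = fhn_params(), t_end = 420, side = 60,
                       stab_tol = 0.05) {
  speeds <- numeric(length(grid_counts))
  for (k in seq_along(grid_counts)) {
    gc <- grid_counts[k]
    g <- make_regular_grid(rbind(rep(0, 3), rep(side, 3)), gc)
    run <- cube_wave_run(g$cloud, g$domain, gc - 1L, scenario,
                         points_per_axis, d_max, kind, fhn,
                         t_end = t_end, side = side)
    speeds[k] <- run$speed
  }
  # stabilization over the propagating part of the curve (coarse lattices may
  # fail to propagate; their speed is NA)
  rel <- abs(diff(speeds)) / abs(speeds[-1])
  stab <- NA_integer_
  for (k in seq_along(rel)) {
    if (all(is.finite(rel[k:length(rel)])) && all(rel[k:length(rel)] < stab_tol)) {
      stab <- grid_counts[k]; break
    }
  }
  rep <- experiment_report(
    data.frame(n_per_axis = grid_counts, speed = speeds,
               h = side / (grid_counts - 1), rms = NA_real_),
    list(points_per_axis = points_per_axis, scenario = scenario,
         d_max = d_max, kind = kind, t_end = t_end, side = side,
         stab_tol = stab_tol))
  rep$stabilization <- stab
  rep
}

#' Synthetic-ventricle activation experiment
#'
#' Builds the idealized ventricular shell, stimulates a handful of
#' endocardial clusters (a stand-in for Purkinje extremities) with
#' v_m = 0.5, and integrates the anisotropic FHN monodomain system. Reports
#' whether the whole shell is captured and whether endocardium leads
#' epicardium at matched transmural depths.
#'
#' @param n target node count.
#' @param seed RNG seed for node placement and nothing else.
#' @param n_clusters number of endocardial stimulus sites.
#' @param stim_radius radius of each stimulated cluster, mm.
#' @param stim_duration duration the cluster potential is held at 0.5, ms
#'   (sustained Purkinje-like drive; an unclamped 0.5 blob of this size is
#'   below the medium's critical nucleus and dies out).
#' @param d_max,kind,points_per_axis,cells_per_axis discretization settings.
#' @param fhn a [fhn_params()] (sigma_f = 4, sigma_cf = 1 defaults).
#' @param t_end simulation window, ms.
#' @param isotropic if TRUE the run is repeated with an isotropic tensor
#'   (sensitivity check).
#' @param shell_args list of overrides passed to [make_ventricle_shell()].
#' @return list: `map`, `trace`, `transmural`, `mean_endo`, `mean_epi`,
#'   `fraction_activated`, `cloud`, `config`.
#' @export
run_ventricle <- function(n = 3164, seed = 2, n_clusters = 6, stim_radius = 9,
                          stim_duration = 20, d_max = 2.5, kind = "cubic",
                          points_per_axis = 3,
                          cells_per_axis = 12, fhn = fhn_params(),
                          t_end = 250, isotropic = FALSE, shell_args = list()) {
  shell <- do.call(make_ventricle_shell, c(list(n = n, seed = seed), shell_args))
  params <- if (isotropic) diffusion_params(fhn$sigma_cf, fhn$sigma_cf, isotropic = TRUE)
            else diffusion_params(fhn$sigma_f, fhn$sigma_cf)
  mesh <- build_background_mesh(shell$domain, cells_per_axis)
  sys <- assemble(shell$cloud, shell$domain, mesh, points_per_axis, d_max, kind,
                  params = params,
                  fibers = if (isotropic) NULL else shell$fibers)
  pos <- shell$cloud$positions
  endo <- which(shell$transmural <= 0.25)
  theta <- atan2(pos[endo, 2], pos[endo, 1])
  ord <- endo[order(theta)]
  centers <- ord[round(seq(1, length(ord), length.out = n_clusters + 1L))[seq_len(n_clusters)]]
  stim <- logical(n_nodes(shell$cloud))
  for (cc in centers) {
    dv <- pos - rep(pos[cc, ], each = nrow(pos))
    stim <- stim | (rowSums(dv^2) <= stim_radius^2 & shell$transmural <= 0.4)
  }
  v0 <- rep(0, n_nodes(shell$cloud))
  v0[stim] <- 0.5
  rhs <- make_rhs(sys, "fhn", fhn)
  # phase 1: sustained (clamped) endocardial drive - a localized blob of
  # amplitude 0.5 alone is below the critical nucleus of this medium, so the
  # Purkinje-site stand-in holds the potential up for stim_duration
  dtA <- 0.4 * stable_euler_dt(sys)
  nA <- ceiling(stim_duration / dtA)
  trA <- integrate_euler(list(v = v0, i = rep(0, length(v0))), dtA, nA, rhs,
                         record_every = max(1L, round(0.5 / dtA)),
                         clamp = list(idx = which(stim), value = 0.5,
                                      until = stim_duration))
  stA <- list(v = trA$V[nrow(trA$V), ], i = trA$I[nrow(trA$I), ])
  tA <- trA$times[length(trA$times)]
  trB <- integrate_rk4_adaptive(stA, c(tA, t_end), rhs, dt0 = 2 * dtA)
  tr <- sim_trace(c(trA$times, trB$times[-1]), rbind(trA$V, trB$V[-1, ]),
                  rbind(trA$I, trB$I[-1, ]),
                  stats = list(steps = trA$stats$steps + trB$stats$steps,
                               rejected = trB$stats$rejected,
                               method = "euler+rk4_adaptive"))
  map <- activation_times(tr, v_threshold = 0.5)
  map$time[stim] <- NA_real_        # clamped nodes: no genuine upstroke
  map$not_activated[stim] <- TRUE
  act <- !map$not_activated
  endo_sel <- shell$transmural <= 0.3
  epi_sel <- shell$transmural >= 0.7
  list(map = map, trace = tr, transmural = shell$transmural,
       mean_endo = mean(map$time[endo_sel & act]),
       mean_epi = mean(map$time[epi_sel & act]),
       # capture fraction over the tissue the wave must reach (the clamped
       # stimulus nodes are sources and have no measurable upstroke)
       fraction_activated = mean(act[!stim]),
       stimulated = which(stim),
       cloud = shell$cloud, fibers = shell$fibers, sys = sys,
       config = list(n = n, seed = seed, n_clusters = n_clusters,
                     stim_radius = stim_radius, d_max = d_max, kind = kind,
                     points_per_axis = points_per_axis,
                     cells_per_axis = cells_per_axis, t_end = t_end,
                     isotropic = isotropic))
}
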