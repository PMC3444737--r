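#' Time integration of the semi-discrete monodomain system
#'
#' The assembled weak form reads A_m C_m dv/dt + M^-1 K v = f with
#' f = -A_m I_ion (nodal). M is SPD and constant, so it is factorized once
#' and applied at every step.
#'
#' @name dynamics
#' @keywords internal
NULL

#' Build a right-hand-side closure for a model
#'
#' @param sys an `efgm_system` (or baseline system) with `M`, `K`.
#' @param model `"heat"` (pure diffusion, dv = -M^-1 K v), `"cubic_cable"`
#'   (cubic ionic current; needs [cubic_ionic_params()]) or `"fhn"`
#'   (modified FitzHugh-Nagumo; needs [fhn_params()]; `K` must be assembled
#'   from the FHN diffusivities).
#' @param params model parameters.
#' @return function(state) -> list(dv, di); `state` is a list with `v` and
#'   (for FHN) `i`.
#' @export
make_rhs <- function(sys, model = c("heat", "cubic_cable", "fhn"), params = NULL) {
  model <- match.arg(model)
  msolve <- mass_solver(sys$M)
  K <- sys$K
  diff_term <- function(v) as.numeric(msolve(K %*% v))
  switch(model,
    heat = function(state) list(dv = -diff_term(state$v), di = NULL),
    cubic_cable = {
      stopifnot(inherits(params, "cubic_ionic_params"))
      amcm <- params$A_m * params$C_m
      function(state) {
        v <- state$v
        list(dv = -cubic_current(v, params) / params$C_m - diff_term(v) / amcm,
             di = NULL)
      }
    },
    fhn = {
      stopifnot(inherits(params, "fhn_params"))
      function(state) {
        r <- fhn_rhs(state$v, state$i, params)
        list(dv = r$dv - diff_term(state$v), di = r$di)
      }
    })
}

# one-time sparse Cholesky (or trivial diagonal) solver for the mass matrix
mass_solver <- function(M) {
  if (inherits(M, "diagonalMatrix")) {
    dg <- Matrix::diag(M)
    return(function(b) as.numeric(b) / dg)
  }
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(M), LDL = FALSE)
  function(b) as.numeric(Matrix::solve(ch, b))
}

#' Single forward-Euler step
#'
#' @param state list with `v` (and `i` for FHN).
#' @param dt time step, ms (> 0).
#' @param rhs right-hand side closure from [make_rhs()].
#' @return updated state.
#' @export
step_euler <- function(state, dt, rhs) {
  stopifnot(dt > 0)
  r <- rhs(state)
  v <- state$v + dt * r$dv
  i <- if (!is.null(state$i)) state$i + dt * r$di else NULL
  if (!all(is.finite(v)))
    stop(sprintf("step_euler: blow-up (max |v| = %g)", max(abs(v), na.rm = TRUE)))
  list(v = v, i = i)
}

#' Forward-Euler integration with trace recording
#'
#' @param state0 initial state, list with `v` (and `i` for FHN).
#' @param dt step size, ms.
#' @param n_steps number of steps.
#' @param rhs closure from [make_rhs()].
#' @param t0 initial time, ms.
#' @param record_every record the state every this many steps (1 = all).
#' @param clamp optional held stimulus, list(idx, value, until): after every
#'   step with t <= until the potential at `idx` is reset to `value`
#'   (current-mode stimulation, e.g. sustained Purkinje drive).
#' @return a `sim_trace`: `times` (ms), `V` (samples x nodes), `I` (or NULL),
#'   `stats`.
#' @export
integrate_euler <- function(state0, dt, n_steps, rhs, t0 = 0, record_every = 1L,
                            clamp = NULL) {
  n_rec <- floor(n_steps / record_every) + 1L
  V <- matrix(0, n_rec, length(state0$v))
  I <- if (!is.null(state0$i)) matrix(0, n_rec, length(state0$i)) else NULL
  times <- numeric(n_rec)
  V[1L, ] <- state0$v
  if (!is.null(I)) I[1L, ] <- state0$i
  times[1L] <- t0
  st <- state0
  rec <- 1L
  for (s in seq_len(n_steps)) {
    st <- step_euler(st, dt, rhs)
    if (!is.null(clamp) && t0 + s * dt <= clamp$until)
      st$v[clamp$idx] <- clamp$value
    if (s %% record_every == 0L) {
      rec <- rec + 1L
      V[rec, ] <- st$v
      if (!is.null(I)) I[rec, ] <- st$i
      times[rec] <- t0 + s * dt
    }
  }
  sim_trace(times[seq_len(rec)], V[seq_len(rec), , drop = FALSE],
            if (!is.null(I)) I[seq_len(rec), , drop = FALSE],
            stats = list(steps = n_steps, rejected = 0L, method = "euler", dt = dt))
}

sim_trace <- function(times, V, I = NULL, stats = list()) {
  stopifnot(all(diff(times) > 0), nrow(V) == length(times))
  structure(list(times = times, V = V, I = I, stats = stats),
            class = "sim_trace")
}

#' @export
print.sim_trace <- function(x, ...) {
  cat(sprintf("<sim_trace> %d samples on [%.3g, %.3g] ms, %d nodes (%s, %d steps, %d rejected)\n",
              length(x$times), x$times[1], x$times[length(x$times)], ncol(x$V),
              x$stats$method %||% "?", x$stats$steps %||% NA,
              x$stats$rejected %||% 0L))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Adaptive fourth-order Runge-Kutta integration
#'
#' Classical RK4 with step-doubling error control: each step is taken once
#' with dt and twice with dt/2; the scaled difference drives acceptance and
#' the next step size, and the accepted state is the locally extrapolated
#' fifth-order combination. Snapshots at requested times are produced by
#' linear interpolation between accepted steps. Deterministic for fixed
#' inputs.
#'
#' @param state0 initial state.
#' @param t_span length-2 vector (t0, t_end), ms.
#' @param rhs closure from [make_rhs()].
#' @param rtol,atol relative/absolute error tolerances.
#' @param dt0 initial step, ms.
#' @param dt_min step underflow bound; going below raises a stiffness error.
#' @param snapshot_times optional times (ms) at which interpolated states are
#'   returned in the trace (in addition to the accepted steps).
#' @return a `sim_trace` (accepted steps; `snapshots` attribute holds the
#'   interpolated states when `snapshot_times` is given).
#' @export
integrate_rk4_adaptive <- function(state0, t_span, rhs, rtol = 1e-5, atol = 1e-7,
                                   dt0 = NULL, dt_min = 1e-8,
                                   snapshot_times = NULL) {
  stopifnot(rtol > 0, atol > 0)
  t0 <- t_span[1]; t_end <- t_span[2]
  dt <- dt0 %||% ((t_end - t0) / 100)
  pack <- function(s) c(s$v, s$i)
  nv <- length(state0$v)
  unpack <- function(y) list(v = y[seq_len(nv)],
                             i = if (length(y) > nv) y[-seq_len(nv)] else NULL)
  f <- function(y) {
    r <- rhs(unpack(y))
    c(r$dv, r$di)
  }
  rk4 <- function(y, h) {
    k1 <- f(y)
    k2 <- f(y + h / 2 * k1)
    k3 <- f(y + h / 2 * k2)
    k4 <- f(y + h * k3)
    y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y <- pack(state0)
  t <- t0
  times <- t
  Y <- list(y)
  accepted <- 0L; rejected <- 0L
  while (t < t_end - 1e-12) {
    h <- min(dt, t_end - t)
    y1 <- rk4(y, h)
    ym <- rk4(y, h / 2)
    y2 <- rk4(ym, h / 2)
    sc <- atol + rtol * pmax(abs(y), abs(y2))
    err <- max(abs(y1 - y2) / sc) / 15
    if (!is.finite(err)) err <- 2
    if (err <= 1) {
      y <- y2 + (y2 - y1) / 15
      t <- t + h
      accepted <- accepted + 1L
      times <- c(times, t)
      Y[[length(Y) + 1L]] <- y
    } else {
      rejected <- rejected + 1L
    }
    fac <- if (err > 0) 0.9 * err^(-0.2) else 2
    dt <- h * min(2, max(0.2, fac))
    if (dt < dt_min)
      stop(sprintf("integrate_rk4_adaptive: step underflow (dt = %g ms at t = %g): system too stiff for the tolerances", dt, t))
  }
  V <- do.call(rbind, lapply(Y, function(y) y[seq_len(nv)]))
  I <- if (length(Y[[1]]) > nv)
    do.call(rbind, lapply(Y, function(y) y[-seq_len(nv)])) else NULL
  tr <- sim_trace(times, V, I,
                  stats = list(steps = accepted, rejected = rejected,
                               method = "rk4_adaptive", rtol = rtol, atol = atol))
  if (!is.null(snapshot_times)) {
    snaps <- lapply(snapshot_times, function(ts) {
      k <- findInterval(ts, times, all.inside = TRUE)
      w <- (ts - times[k]) / (times[k + 1] - times[k])
      list(time = ts, v = (1 - w) * V[k, ] + w * V[k + 1, ],
           i = if (!is.null(I)) (1 - w) * I[k, ] + w * I[k + 1, ] else NULL)
    })
    attr(tr, "snapshots") <- snaps
  }
  tr
}

#' Activation times from a simulation trace
#'
#' The activation time of a node is the time of maximum upstroke velocity
#' (maximum centered finite-difference dv/dt along the trace), with ties
#' broken by the earliest time. Optionally the discrete maximum is refined by
#' a parabola through the neighbouring samples. Nodes whose potential never
#' exceeds `v_threshold` are flagged `not_activated`.
#'
#' @param trace a `sim_trace` (>= 3 samples).
#' @param v_threshold fallback capture threshold; default 50% of the
#'   excitation amplitude observed in the trace.
#' @param refine parabolic sub-sample refinement of the peak (default TRUE).
#' @return an `activation_map`: data.frame with `time` (ms) and
#'   `not_activated`.
#' @export
activation_times <- function(trace, v_threshold = NULL, refine = TRUE) {
  tt <- trace$times
  V <- trace$V
  stopifnot(length(tt) >= 3)
  if (is.null(v_threshold)) {
    lo <- min(V); hi <- max(V)
    v_threshold <- lo + 0.5 * (hi - lo)
  }
  ns <- length(tt)
  dVdt <- (V[3:ns, , drop = FALSE] - V[1:(ns - 2), , drop = FALSE]) /
    (tt[3:ns] - tt[1:(ns - 2)])
  tmid <- tt[2:(ns - 1)]
  kmax <- apply(dVdt, 2, which.max)          # first maximum on ties
  at <- tmid[kmax]
  if (refine) {
    for (j in seq_along(kmax)) {
      k <- kmax[j]
      if (k > 1 && k < nrow(dVdt)) {
        # parabola vertex in centered time coordinates (conditioning)
        s <- tmid[(k - 1):(k + 1)] - tmid[k]
        g3 <- dVdt[(k - 1):(k + 1), j]
        co <- tryCatch(stats::lm.fit(cbind(1, s, s^2), g3)$coefficients,
                       error = function(e) NULL)
        if (!is.null(co) && is.finite(co[3]) && co[3] < 0) {
          sv <- -co[2] / (2 * co[3])
          if (sv >= s[1] && sv <= s[3]) at[j] <- tmid[k] + sv
        }
      }
    }
  }
  notact <- apply(V, 2, max) < v_threshold
  at[notact] <- NA_real_
  structure(data.frame(time = at, not_activated = notact),
            class = c("activation_map", "data.frame"))
}

#' Node-wise conduction velocity along an axis
#'
#' Velocity at a node is the centered difference of position versus
#' activation time along the propagation axis. Nodes within `trim_fraction`
#' of either end of the axis extent are excluded (boundary effects), as are
#' non-activated nodes. The summary gives the mean velocity and, when a
#' `reference` speed is supplied, the root-mean-square error
#' RMS = sqrt(mean((reference - velocity_i)^2)).
#'
#' @param map an [activation_times()] result.
#' @param positions node coordinate matrix (or vector in 1D), mm.
#' @param axis axis index along which the wave travels.
#' @param trim_fraction fraction of the extent trimmed at each end.
#' @param reference optional reference velocity, mm/ms.
#' @return list with `velocity` (per included node), `nodes` (their indices),
#'   `mean`, `rms` (NA without a reference).
#' @export
conduction_velocity <- function(map, positions, axis = 1, trim_fraction = 0.1,
                                reference = NULL) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 1)
  x <- positions[, axis]
  act <- which(!map$not_activated)
  if (length(act) < 3) stop("conduction_velocity: fewer than 3 activated nodes")
  ord <- act[order(x[act])]
  xs <- x[ord]; ts <- map$time[ord]
  n <- length(ord)
  vel <- rep(NA_real_, n)
  dt2 <- ts[3:n] - ts[1:(n - 2)]
  vel[2:(n - 1)] <- ifelse(dt2 != 0, (xs[3:n] - xs[1:(n - 2)]) / dt2, NA)
  lo <- min(x) + trim_fraction * (max(x) - min(x))
  hi <- max(x) - trim_fraction * (max(x) - min(x))
  keep <- which(xs >= lo & xs <= hi & is.finite(vel))
  if (length(keep) < 3) stop("conduction_velocity: fewer than 3 usable nodes after trimming")
  v <- vel[keep]
  list(velocity = v, nodes = ord[keep], mean = mean(v),
       rms = if (is.null(reference)) NA_real_ else rms_error(reference, v))
}

#' Root-mean-square error between exact and numerical values
#' @param exact,numerical numeric vectors (exact may be scalar).
#' @return sqrt(mean((exact - numerical)^2))
#' @export
rms_error <- function(exact, numerical) sqrt(mean((exact - numerical)^2))
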