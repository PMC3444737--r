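#' Cubic polynomial ionic model parameters
#'
#' The cubic current I_ion = g v (1 - v/v_th)(1 - v/v_p) has rest, threshold
#' and plateau as its three roots. All potentials are handled internally as
#' deviations from rest: the published absolute values (rest -85 mV,
#' threshold -75 mV, plateau +15 mV) give the defaults v_th = 10 mV,
#' v_p = 100 mV.
#'
#' @param g membrane conductance, mS/mm^2.
#' @param v_th,v_p threshold and plateau potentials (deviations from rest),
#'   mV; must satisfy 0 < v_th < v_p.
#' @param C_m membrane capacitance, uF/mm^2.
#' @param A_m surface-to-volume ratio, 1/mm.
#' @param v_rest resting potential, mV (bookkeeping only).
#' @return object of class `cubic_ionic_params`.
#' @export
cubic_ionic_params <- function(g = 0.004, v_th = 10, v_p = 100,
                               C_m = 0.01, A_m = 200, v_rest = -85) {
  if (!(0 < v_th && v_th < v_p)) stop("cubic_ionic_params: need 0 < v_th < v_p")
  if (g <= 0 || C_m <= 0 || A_m <= 0)
    stop("cubic_ionic_params: g, C_m, A_m must be positive")
  structure(list(g = g, v_th = v_th, v_p = v_p, C_m = C_m, A_m = A_m,
                 v_rest = v_rest), class = "cubic_ionic_params")
}

#' Cubic ionic current
#'
#' I_ion = g v (1 - v/v_th)(1 - v/v_p), elementwise; positive (outward,
#' repolarizing) below threshold and negative (depolarizing) between
#' threshold and plateau.
#'
#' @param v_m transmembrane potential deviation(s) from rest, mV.
#' @param params a [cubic_ionic_params()]
#' @return ionic current, uA/mm^2.
#' @export
cubic_current <- function(v_m, params) {
  params$g * v_m * (1 - v_m / params$v_th) * (1 - v_m / params$v_p)
}

#' Closed-form conduction velocity of the cubic-model cable
#'
#' The monodomain cable with the cubic ionic current is a bistable
#' reaction-diffusion equation whose traveling front has the exact speed
#' gamma = sqrt(g sigma / (A_m C_m^2)) * S / sqrt(S + 1) with
#' S = v_p / (2 v_th) - 1. The speed scales exactly as sqrt(sigma).
#'
#' @param params a [cubic_ionic_params()]
#' @param sigma cable conductivity, mS/mm.
#' @return conduction velocity, mm/ms.
#' @export
analytic_velocity <- function(params, sigma) {
  S <- params$v_p / (2 * params$v_th) - 1
  if (S <= 0)
    stop("analytic_velocity: no propagating front (v_p <= 2 v_th)")
  sqrt(params$g * sigma / (params$A_m * params$C_m^2)) * S / sqrt(S + 1)
}

#' Modified FitzHugh-Nagumo parameters
#'
#' Two-variable excitable-membrane model: excitation v_m (dimensionless,
#' about 0..1) and recovery current I_ion. Defaults are the published values
#' a = 0.13, b = 0.013, c1 = 0.26, c2 = 0.1, d = 1.0 with diffusivities
#' sigma_f = 4, sigma_cf = 1 (mm^2/ms); time is in ms.
#'
#' @param a,b,c1,c2,d dimensionless shape parameters.
#' @param sigma_f,sigma_cf diffusivities along/across fiber, mm^2/ms.
#' @return object of class `fhn_params`.
#' @export
fhn_params <- function(a = 0.13, b = 0.013, c1 = 0.26, c2 = 0.1, d = 1.0,
                       sigma_f = 4.0, sigma_cf = 1.0) {
  vals <- c(a, b, c1, c2, d, sigma_f, sigma_cf)
  if (!all(is.finite(vals))) stop("fhn_params: non-finite parameter")
  structure(list(a = a, b = b, c1 = c1, c2 = c2, d = d,
                 sigma_f = sigma_f, sigma_cf = sigma_cf),
            class = "fhn_params")
}

#' FitzHugh-Nagumo reaction right-hand side
#'
#' f(v, i) = c1 v (v - a)(1 - v) - c2 v i,  di/dt = b (v - d i),
#' evaluated elementwise. Rest (0, 0) is an equilibrium; v = a is the
#' excitation threshold.
#'
#' @param v_m excitation variable (vector).
#' @param i_ion recovery variable (vector).
#' @param params a [fhn_params()]
#' @return list with `dv` (reaction part of dv_m/dt) and `di`.
#' @export
fhn_rhs <- function(v_m, i_ion, params) {
  list(dv = params$c1 * v_m * (v_m - params$a) * (1 - v_m) -
         params$c2 * v_m * i_ion,
       di = params$b * (v_m - params$d * i_ion))
}
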