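#' Anisotropic diffusion tensors from fiber orientation
#'
#' Conduction in myocardium is fastest along the local myofiber direction.
#' In the fiber frame the diffusion tensor is diagonal,
#' D_local = diag(sigma_f, sigma_cf, sigma_cf), and the global tensor is
#' obtained by rotating the first axis onto the fiber: D = T D_local T^-1.
#'
#' @name anisotropy
#' @keywords internal
NULL

#' Diffusion (conductivity) parameters
#'
#' @param sigma_f conductivity/diffusivity along the fiber (> 0). Units follow
#'   the active model: mS/mm for the cable model, mm^2/ms diffusivity for the
#'   FitzHugh-Nagumo model.
#' @param sigma_cf value across the fiber (> 0).
#' @param isotropic if `TRUE` the tensor is `sigma_cf * I` everywhere.
#' @return object of class `diffusion_params`.
#' @export
diffusion_params <- function(sigma_f, sigma_cf = sigma_f, isotropic = FALSE) {
  if (sigma_f <= 0 || sigma_cf <= 0)
    stop("diffusion_params: conductivities must be positive")
  structure(list(sigma_f = sigma_f, sigma_cf = sigma_cf, isotropic = isotropic),
            class = "diffusion_params")
}

#' Fiber-frame (local) diffusion tensor
#'
#' @param params a [diffusion_params()]
#' @param dim 1, 2 or 3.
#' @return d x d matrix diag(sigma_f, sigma_cf, ...).
#' @export
local_tensor <- function(params, dim) {
  stopifnot(dim %in% 1:3)
  diag(c(params$sigma_f, rep(params$sigma_cf, dim - 1L)), nrow = dim)
}

# rotations about z (alpha) and y (beta) as used for fiber frames
rot_xy <- function(alpha) {
  ca <- cos(alpha); sa <- sin(alpha)
  matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3)
}
rot_xz <- function(beta) {
  cb <- cos(beta); sb <- sin(beta)
  matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3, 3)
}

#' Rotate a local diffusion tensor into the global frame
#'
#' D = T D_local T^-1 with T = R_xz(beta) R_xy(alpha); alpha rotates about z,
#' beta about y. T is orthogonal, so T^-1 = T^T.
#'
#' @param local d x d local tensor (from [local_tensor()]).
#' @param alpha,beta rotation angles, radians. In 2D only `alpha` is used.
#' @return d x d symmetric tensor.
#' @export
rotate_tensor <- function(local, alpha, beta = 0) {
  d <- nrow(local)
  if (d == 1L) return(local)
  if (d == 2L) {
    ca <- cos(alpha); sa <- sin(alpha)
    T2 <- matrix(c(ca, sa, -sa, ca), 2, 2)
    return(T2 %*% local %*% t(T2))
  }
  T3 <- rot_xz(beta) %*% rot_xy(alpha)
  T3 %*% local %*% t(T3)
}

#' Diffusion tensor with its fast axis along a given fiber
#'
#' Finds the rotation angles (alpha about z, beta about y) mapping the first
#' local axis onto the unit fiber vector and applies [rotate_tensor()], so
#' that D f = sigma_f f.
#'
#' @param params a [diffusion_params()]
#' @param fiber unit vector, length 2 or 3.
#' @return d x d symmetric tensor.
#' @export
fiber_to_tensor <- function(params, fiber) {
  fiber <- as.numeric(fiber)
  d <- length(fiber)
  if (abs(sqrt(sum(fiber^2)) - 1) > 1e-8)
    stop("fiber_to_tensor: fiber vector must be unit length")
  if (params$isotropic) return(diag(params$sigma_cf, d))
  if (d == 2L)
    return(rotate_tensor(local_tensor(params, 2L), atan2(fiber[2], fiber[1])))
  # T e1 = (cos b cos a, -sin a, -sin b cos a); match to the fiber
  sa <- -fiber[2]
  ca <- sqrt(max(0, 1 - sa^2))
  if (ca < 1e-12) {                      # fiber parallel to y-axis
    alpha <- if (fiber[2] > 0) -pi / 2 else pi / 2
    beta <- 0
  } else {
    alpha <- atan2(sa, ca)
    beta <- atan2(-fiber[3] / ca, fiber[1] / ca)
  }
  rotate_tensor(local_tensor(params, 3L), alpha, beta)
}

#' Diffusion tensor at an arbitrary point by fiber interpolation
#'
#' The nodal fiber vectors are interpolated with the MLS shape functions of
#' the evaluation point and renormalized to unit length; the tensor is then
#' built for the interpolated direction. If opposing fibers cancel (norm of
#' the interpolated vector < 1e-6, as can happen across an abrupt fiber
#' discontinuity), the nearest contributing node's fiber is used instead and
#' a message is logged.
#'
#' @param shape_eval a [mls_shape()] result at the point.
#' @param fibers a [fiber_field()]
#' @param params a [diffusion_params()]
#' @param cloud the [node_cloud()] the shape functions were built on.
#' @return d x d symmetric tensor.
#' @export
tensor_field <- function(shape_eval, fibers, params, cloud) {
  d <- cloud$dim
  if (params$isotropic || fibers$isotropic) return(diag(params$sigma_cf, d))
  idx <- shape_eval$node_indices
  f <- drop(shape_eval$phi %*% fibers$vectors[idx, , drop = FALSE])
  nf <- sqrt(sum(f^2))
  if (nf < 1e-6) {
    dv <- cloud$positions[idx, , drop = FALSE] -
      rep(shape_eval$point, each = length(idx))
    near <- idx[which.min(rowSums(dv^2))]
    message(sprintf(
      "tensor_field: interpolated fiber cancelled at (%s); using nearest node %d",
      paste(signif(shape_eval$point, 5), collapse = ", "), near - 1L))
    f <- fibers$vectors[near, ]
    nf <- sqrt(sum(f^2))
  }
  # sigma_cf I + (sigma_f - sigma_cf) f f^T == T D_local T^T for unit f
  f <- f / nf
  diag(params$sigma_cf, d) + (params$sigma_f - params$sigma_cf) * tcrossprod(f)
}
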