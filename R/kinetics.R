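#' Reaction rates of the well-mixed model
#'
#' Evaluates the diffusion-free kinetics of the tumour-immune model at a
#' state `(u, v, w)`:
#' \deqn{\dot u = \alpha v - \mu_u u + \rho_u u w / (1 + w) + \sigma_u}
#' \deqn{\dot v = v(1 - v) - u v / (\gamma_v + v)}
#' \deqn{\dot w = \rho_w u v / (\gamma_w + v) - \mu_w w + \sigma_w}
#'
#' @param state numeric length-3 vector `(u, v, w)`.
#' @param params a [nondim_params()] object.
#' @param sigma_u,sigma_w optional instantaneous treatment inputs overriding
#'   the values stored in `params` (used by time-dependent protocols).
#' @return Numeric length-3 vector of time derivatives.
#' @export
reaction_rates <- function(state, params, sigma_u = params$sigma_u,
                           sigma_w = params$sigma_w) {
  u <- state[[1]]; v <- state[[2]]; w <- state[[3]]
  if (!all(is.finite(c(u, v, w)))) stop("state must be finite")
  if (1 + w <= 0 || params$gamma_v + v <= 0 || params$gamma_w + v <= 0)
    stop("non-positive denominator: state outside the model's domain")
  # note: sigma_u/sigma_w are taken from the arguments, not from params,
  # so time-dependent protocols can inject instantaneous values
  c(params$alpha * v - params$mu_u * u +
      params$rho_u * u * w / (1 + w) + sigma_u,
    v * (1 - v) - u * v / (params$gamma_v + v),
    params$rho_w * u * v / (params$gamma_w + v) - params$mu_w * w + sigma_w)
}

#' Jacobian of the well-mixed kinetics
#'
#' Closed-form 3x3 Jacobian of [reaction_rates()] with respect to
#' `(u, v, w)`. The `(2,3)` entry is identically zero: the tumour equation
#' does not involve IL-2 directly.
#'
#' @inheritParams reaction_rates
#' @return A 3x3 numeric matrix.
#' @export
reaction_jacobian <- function(state, params) {
  u <- state[[1]]; v <- state[[2]]; w <- state[[3]]
  if (1 + w <= 0 || params$gamma_v + v <= 0 || params$gamma_w + v <= 0)
    stop("non-positive denominator: state outside the model's domain")
  with(params, matrix(c(
    rho_u * w / (w + 1) - mu_u,
    alpha,
    rho_u * u / (w + 1) - rho_u * u * w / (w + 1)^2,
    -v / (gamma_v + v),
    u * v / (gamma_v + v)^2 - u / (gamma_v + v) - 2 * v + 1,
    0,
    rho_w * v / (gamma_w + v),
    rho_w * u / (gamma_w + v) - rho_w * u * v / (gamma_w + v)^2,
    -mu_w), nrow = 3, byrow = TRUE))
}
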