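#' Nondimensional model parameters
#'
#' Construct the full set of nondimensional parameters of the tumour-immune
#' reaction-diffusion model. The tumour species' own diffusivity is the unit
#' of diffusion and is therefore not a field; `delta_u` and `delta_w` are the
#' effector-cell and IL-2 diffusivities relative to it.
#'
#' @param delta_u,delta_w relative diffusivities of effector cells and IL-2
#'   (dimensionless, >= 0).
#' @param alpha immune-response strength (tumour-stimulated effector
#'   recruitment).
#' @param mu_u,mu_w effector and IL-2 decay rates.
#' @param rho_u,rho_w IL-2-stimulated effector proliferation rate and
#'   effector-tumour-stimulated IL-2 production rate.
#' @param sigma_u,sigma_w treatment inputs: external effector-cell and IL-2
#'   sources.
#' @param gamma_v,gamma_w half-saturation densities of the effector-kill and
#'   IL-2-production terms.
#' @return An object of class `nondim_params` (a named list).
#' @export
nondim_params <- function(delta_u = 100, delta_w = 100, alpha = 0.07,
                          mu_u = 0.167, mu_w = 55.56,
                          rho_u = 0.692, rho_w = 2.5,
                          sigma_u = 0, sigma_w = 0,
                          gamma_v = 0.1, gamma_w = 1e-3) {
  p <- list(delta_u = delta_u, delta_w = delta_w, alpha = alpha,
            mu_u = mu_u, mu_w = mu_w, rho_u = rho_u, rho_w = rho_w,
            sigma_u = sigma_u, sigma_w = sigma_w,
            gamma_v = gamma_v, gamma_w = gamma_w)
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all nondimensional parameters must be finite and >= 0")
  structure(p, class = "nondim_params")
}

#' @export
print.nondim_params <- function(x, ...) {
  cat("Nondimensional tumour-immune model parameters:\n")
  print(unlist(x))
  invisible(x)
}

#' Dimensional model parameters
#'
#' Dimensional parameter set for the tumour-immune model. These exist for
#' provenance (the published parameter table) and for the diffusivity
#' estimators; all analysis runs on [nondim_params()].
#'
#' @param d_E,d_T,d_IL diffusivities (cm^2/day) of effector cells, tumour
#'   cells and IL-2.
#' @param c immune-response rate (1/day, >= 0).
#' @param m_E,m_IL decay rates (1/day).
#' @param p_E,p_T,p_IL interaction rates (1/day).
#' @param g_E,g_T,g_IL half-saturation densities (cells/cm).
#' @param s_E,s_IL treatment source rates (>= 0).
#' @param r_T tumour growth rate (1/day).
#' @param b inverse carrying capacity (cm/cell).
#' @return An object of class `dim_params`.
#' @export
dimensional_params <- function(d_E, d_T, d_IL, c, m_E, m_IL,
                               p_E, p_T, p_IL, g_E, g_T, g_IL,
                               s_E = 0, s_IL = 0, r_T, b) {
  p <- list(d_E = d_E, d_T = d_T, d_IL = d_IL, c = c, m_E = m_E,
            m_IL = m_IL, p_E = p_E, p_T = p_T, p_IL = p_IL, g_E = g_E,
            g_T = g_T, g_IL = g_IL, s_E = s_E, s_IL = s_IL,
            r_T = r_T, b = b)
  vals <- unlist(p)
  if (any(!is.finite(vals))) stop("dimensional parameters must be finite")
  nonneg_ok <- c("s_E", "s_IL", "c")
  strict <- vals[setdiff(names(p), nonneg_ok)]
  if (any(strict <= 0) || any(vals[nonneg_ok] < 0))
    stop("dimensional parameters must be positive (s_E, s_IL, c may be zero)")
  structure(p, class = "dim_params")
}

#' Reference dimensional parameter set
#'
#' The published dimensional parameter values (point estimates; for ranged
#' parameters the value used in the simulations, with the ranges available
#' via `attr(x, "ranges")`). Diffusivities default to the tumour-cell
#' estimate `d_T = 1.21e-6` cm^2/day and relative diffusivities
#' `delta_u = delta_w = 100`.
#'
#' @param c immune-response rate (1/day); the published range is 0 to 0.05.
#' @param s_E,s_IL treatment sources (default 0).
#' @param delta_u,delta_w requested relative diffusivities, used to set
#'   `d_E = delta_u * d_T` and `d_IL = delta_w * d_T`.
#' @return A `dim_params` object with a `ranges` attribute.
#' @export
reference_dimensional <- function(c = 0.07 * 0.18^2 / 0.1, s_E = 0, s_IL = 0,
                               delta_u = 100, delta_w = 100) {
  d_T <- 1.21e-6
  p <- dimensional_params(
    d_E = delta_u * d_T, d_T = d_T, d_IL = delta_w * d_T, c = c,
    m_E = 0.03, m_IL = 10, p_E = 0.1245, p_T = 0.1, p_IL = 5,
    g_E = 2e7, g_T = 1e5, g_IL = 1e3, s_E = s_E, s_IL = s_IL,
    r_T = 0.18, b = 1e-6)
  attr(p, "ranges") <- list(d_E = c(7e-5, 1e-2), d_T = c(1.21e-6, 9.375e-5),
                            d_IL = c(1e-4, 1e-2), c = c(0, 0.05))
  p
}

#' Reference nondimensional parameter set
#'
#' The published nondimensional values: these are the rounded values as
#' printed (`mu_u = 0.167`, `rho_u = 0.692`, `mu_w = 55.56`), which are the
#' values all quantitative results in this package are benchmarked against.
#'
#' @param ... overrides passed to [nondim_params()] (typically `alpha`,
#'   `sigma_u`, `sigma_w`, `delta_u`, `delta_w`).
#' @return A `nondim_params` object.
#' @export
reference_nondim <- function(...) {
  defaults <- list(delta_u = 100, delta_w = 100, alpha = 0.07,
                   mu_u = 0.167, mu_w = 55.56, rho_u = 0.692, rho_w = 2.5,
                   sigma_u = 0, sigma_w = 0, gamma_v = 0.1, gamma_w = 1e-3)
  do.call(nondim_params, modifyList(defaults, list(...)))
}

#' Nondimensionalise a dimensional parameter set
#'
#' Applies the model's scalings: time in units of the tumour growth timescale
#' `1/r_T`, length in units of `sqrt(d_T/r_T)`, tumour density in units of
#' the carrying capacity `1/b`, effector density in units of `r_T/(b p_T)`
#' and IL-2 in units of `g_E`.
#'
#' @param dim a `dim_params` object.
#' @return A list with elements `params` ([nondim_params()]) and `scales`
#'   (named list `E0`, `T0`, `IL0`, `t_s`, `X`).
#' @export
nondimensionalise <- function(dim) {
  stopifnot(inherits(dim, "dim_params"))
  with(dim, {
    if (min(r_T, b, p_T, g_E, d_T) <= 0)
      stop("r_T, b, p_T, g_E, d_T must be positive")
    scales <- list(E0 = r_T / (b * p_T), T0 = 1 / b, IL0 = g_E,
                   t_s = 1 / r_T, X = sqrt(d_T / r_T))
    params <- nondim_params(
      delta_u = d_E / d_T, delta_w = d_IL / d_T,
      alpha = p_T * c / r_T^2,
      mu_u = m_E / r_T, mu_w = m_IL / r_T,
      rho_u = p_E / r_T, rho_w = p_IL / (b * p_T * g_E),
      sigma_u = b * p_T * s_E / r_T^2, sigma_w = s_IL / (g_E * r_T),
      gamma_v = g_T * b, gamma_w = g_IL * b)
    list(params = params, scales = scales)
  })
}

#' Recover dimensional parameters from nondimensional ones
#'
#' Inverts [nondimensionalise()] given the scaling set (the nondimensional
#' parameters alone do not determine the dimensional ones).
#'
#' @param params a `nondim_params` object.
#' @param scales the scaling set returned by [nondimensionalise()].
#' @return A `dim_params` object.
#' @export
redimensionalise <- function(params, scales) {
  r_T <- 1 / scales$t_s
  b <- 1 / scales$T0
  d_T <- scales$X^2 * r_T
  g_E <- scales$IL0
  p_T <- r_T / (b * scales$E0)
  with(params, dimensional_params(
    d_E = delta_u * d_T, d_T = d_T, d_IL = delta_w * d_T, p_T = p_T,
    c = alpha * r_T^2 / p_T, g_E = g_E,
    m_E = mu_u * r_T, m_IL = mu_w * r_T,
    p_E = rho_u * r_T, p_IL = rho_w * b * p_T * g_E,
    g_T = gamma_v / b, g_IL = gamma_w / b,
    s_E = sigma_u * r_T^2 / (b * p_T), s_IL = sigma_w * g_E * r_T,
    r_T = r_T, b = b))
}

# unit conversions and physical constants, centralised
.KB <- 1.380649e-23      # Boltzmann constant, J/K (CODATA)
.M2_TO_CM2 <- 1e4
.S_TO_DAY <- 86400

#' Stokes-Einstein diffusivity estimate
#'
#' Estimates the random-motility coefficient of a spherical cell of radius
#' `R1` in a medium of viscosity `eta` at temperature `temperature` from the
#' Stokes-Einstein relation \eqn{d = k_B T / (6 \pi R_1 \eta)}, converted to
#' cm^2/day.
#'
#' @param temperature absolute temperature (K).
#' @param R1 particle (cell) radius (m).
#' @param eta dynamic viscosity (kg m^-1 s^-1).
#' @return Diffusivity in cm^2/day.
#' @export
stokes_einstein_diffusivity <- function(temperature = 310, R1 = 4e-6,
                                        eta = 6.922e-4) {
  stopifnot(temperature > 0, R1 > 0, eta > 0)
  d_m2_s <- .KB * temperature / (6 * pi * R1 * eta)
  d_m2_s * .M2_TO_CM2 * .S_TO_DAY
}

#' Tumour-cell diffusivity estimate
#'
#' Estimates tumour-cell motility as cell diameter squared times duplication
#' rate, \eqn{d_T = D^2 \lambda}.
#'
#' @param D cell diameter (cm).
#' @param lambda duplication rate (1/day).
#' @return Diffusivity in cm^2/day.
#' @export
tumour_diffusivity <- function(D = 1.1e-3, lambda = 1) {
  stopifnot(D > 0, lambda >= 0)
  D^2 * lambda
}
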