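# Dispersion relation and diffusion-driven (Turing) instability analysis.
#
# Linearising the PDE about a homogeneous state with Fourier modes e^{ikx}
# gives growth rates lambda_k that are eigenvalues of M_k = J - diag(delta_u,
# 1, delta_w) k^2. Their characteristic cubic is
#   lambda^3 + a2 lambda^2 + a1 lambda + a0 = 0,
# and a Turing instability of an ODE-stable state requires a0 < 0 for some
# k^2 > 0 (the other Routh-Hurwitz conditions can only fail through wave
# instabilities, which do not occur in the parameter regimes studied here).

#' Dispersion-cubic coefficients at one wavenumber
#'
#' Coefficients of the characteristic cubic of the linearised spatial
#' operator at wavenumber squared `k2`. The constant term is itself a cubic
#' in `k2`, \eqn{a_0 = A k^6 + B k^4 + C k^2 + D}, whose coefficients are
#' returned as well. The tumour species has unit diffusivity, so the
#' trace-level coefficient is \eqn{(\delta_u + 1 + \delta_w)k^2 - tr(J)}.
#'
#' @param J 3x3 kinetics Jacobian (see [reaction_jacobian()]).
#' @param delta_u,delta_w relative diffusivities.
#' @param k2 wavenumber squared (>= 0, vectorised).
#' @return A list with vectors `a2`, `a1`, `a0` (same length as `k2`) and
#'   scalars `A`, `B`, `C`, `D`.
#' @export
dispersion_coefficients <- function(J, delta_u, delta_w, k2) {
  stopifnot(all(k2 >= 0))
  J11 <- J[1, 1]; J12 <- J[1, 2]; J13 <- J[1, 3]
  J21 <- J[2, 1]; J22 <- J[2, 2]; J23 <- J[2, 3]
  J31 <- J[3, 1]; J32 <- J[3, 2]; J33 <- J[3, 3]
  A <- delta_u * delta_w
  B <- -(delta_u * J33 + delta_u * delta_w * J22 + delta_w * J11)
  C <- delta_u * J22 * J33 + J11 * J33 + delta_w * J11 * J22 -
    delta_u * J23 * J32 - J13 * J31 - delta_w * J12 * J21
  D <- -J11 * J22 * J33 + J11 * J23 * J32 + J12 * J21 * J33 -
    J12 * J23 * J31 - J13 * J21 * J32 + J13 * J22 * J31
  a2 <- (delta_u + 1 + delta_w) * k2 - (J11 + J22 + J33)
  a1 <- (delta_u + delta_u * delta_w + delta_w) * k2^2 -
    (delta_u * (J22 + J33) + (J11 + J33) + delta_w * (J11 + J22)) * k2 +
    J11 * J22 + J11 * J33 + J22 * J33 - J12 * J21 - J13 * J31 - J23 * J32
  a0 <- A * k2^3 + B * k2^2 + C * k2 + D
  list(a2 = a2, a1 = a1, a0 = a0, A = A, B = B, C = C, D = D)
}

#' Growth rates of spatial modes
#'
#' The three roots \eqn{\lambda_k} of the dispersion cubic at wavenumber
#' squared `k2`; the largest real part is the growth rate of that mode.
#'
#' @inheritParams dispersion_coefficients
#' @param k2 scalar wavenumber squared.
#' @return A list with `k2`, `lambdas` (3 complex roots, decreasing real
#'   part) and `max_re`.
#' @export
growth_rates <- function(J, delta_u, delta_w, k2) {
  dc <- dispersion_coefficients(J, delta_u, delta_w, k2)
  lam <- polyroot(c(dc$a0, dc$a1, dc$a2, 1))
  lam <- lam[order(-Re(lam))]
  list(k2 = k2, lambdas = lam, max_re = max(Re(lam)))
}

#' Critical wavenumber of the Turing condition
#'
#' Location of the interior minimum of \eqn{a_0(k^2) = A k^6 + B k^4 +
#' C k^2 + D} over \eqn{k^2 > 0}:
#' \eqn{k_c^2 = (-2B + \sqrt{4B^2 - 12AC}) / (6A)}.
#'
#' @param A,B,C coefficients of the cubic in `k2` (with `A > 0`).
#' @return The critical wavenumber squared.
#' @export
critical_wavenumber <- function(A, B, C) {
  stopifnot(A > 0)
  disc <- 4 * B^2 - 12 * A * C
  if (disc < 0)
    stop("negative discriminant: a0 has no interior extremum in k^2 > 0")
  (-2 * B + sqrt(disc)) / (6 * A)
}

#' Turing-instability test of a homogeneous equilibrium
#'
#' An ODE-stable equilibrium is Turing-unstable iff \eqn{a_0(k_c^2) < 0}.
#' Cancer-free states are never Turing-unstable: any spatial perturbation of
#' `v` about zero would be sign-changing, and the (u,w) subsystem's Jacobian
#' is triangular, so no diffusion-driven instability is available.
#'
#' @param params a [nondim_params()] object (supplies the diffusivities).
#' @param eq an `equilibrium` object.
#' @return A list with logicals `unstable` and `ode_stable`, and (when the
#'   discriminant admits an interior minimum) `k_c2` and `a0_at_kc`.
#' @export
turing_test <- function(params, eq) {
  out <- list(unstable = FALSE, ode_stable = eq$stable,
              k_c2 = NA_real_, a0_at_kc = NA_real_)
  if (eq$kind == "cancer_free" || !eq$stable) return(out)
  J <- reaction_jacobian(eq$state, params)
  dc <- dispersion_coefficients(J, params$delta_u, params$delta_w, 0)
  disc <- 4 * dc$B^2 - 12 * dc$A * dc$C
  if (dc$A <= 0 || disc < 0) return(out)
  kc2 <- critical_wavenumber(dc$A, dc$B, dc$C)
  if (kc2 <= 0) return(out)
  a0c <- dc$A * kc2^3 + dc$B * kc2^2 + dc$C * kc2 + dc$D
  out$k_c2 <- kc2
  out$a0_at_kc <- a0c
  out$unstable <- a0c < 0
  out
}

#' Dispersion curve
#'
#' Maximum growth-rate real part as a function of wavenumber squared.
#'
#' @inheritParams dispersion_coefficients
#' @param k2 numeric vector of wavenumbers squared.
#' @return Data frame with columns `k2`, `max_re`, `is_real` (whether the
#'   leading root is real).
#' @export
dispersion_curve <- function(J, delta_u, delta_w,
                             k2 = seq(0, 2, length.out = 401)) {
  rows <- lapply(k2, function(x) {
    g <- growth_rates(J, delta_u, delta_w, x)
    lead <- g$lambdas[1]
    data.frame(k2 = x, max_re = g$max_re,
               is_real = abs(Im(lead)) < 1e-10 * (1 + abs(Re(lead))))
  })
  do.call(rbind, rows)
}

#' Turing-space scan over the treatment plane
#'
#' Classifies each grid cell of the treatment plane by the most unstable
#' ODE-stable coexistence equilibrium: `no_coexistence` when no stable
#' coexistence state exists, `coex_turing_unstable` when at least one stable
#' coexistence state is Turing-unstable, else `coex_stable_all`.
#'
#' @param params a [nondim_params()] object supplying `alpha`, `delta_u`,
#'   `delta_w` and the kinetics.
#' @param sigma_u,sigma_w ascending numeric grids.
#' @return Character matrix (`length(sigma_u)` x `length(sigma_w)`) with
#'   attributes `sigma_u`, `sigma_w`, `alpha`, `delta_u`, `delta_w`.
#' @export
scan_turing_plane <- function(params,
                              sigma_u = seq(0, 0.05, length.out = 101),
                              sigma_w = seq(0, 20, length.out = 101)) {
  stopifnot(!is.unsorted(sigma_u), !is.unsorted(sigma_w))
  lab <- matrix(NA_character_, length(sigma_u), length(sigma_w))
  for (j in seq_along(sigma_w)) {
    for (i in seq_along(sigma_u)) {
      p <- params
      p$sigma_u <- sigma_u[i]; p$sigma_w <- sigma_w[j]
      eqs <- coexistence_equilibria(p, method = "quintic")
      stable <- Filter(function(e) e$stable, eqs)
      if (!length(stable)) {
        lab[i, j] <- "no_coexistence"
      } else {
        tu <- vapply(stable, function(e) turing_test(p, e)$unstable,
                     logical(1))
        lab[i, j] <- if (any(tu)) "coex_turing_unstable" else
          "coex_stable_all"
      }
    }
  }
  structure(lab, sigma_u = sigma_u, sigma_w = sigma_w, alpha = params$alpha,
            delta_u = params$delta_u, delta_w = params$delta_w)
}
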