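# Homogeneous steady states of the well-mixed model and their stability.
#
# The coexistence states solve a scalar equation in the tumour density v0:
# substituting u0 = (gamma_v + v0)(1 - v0) (from the tumour equation) and
# w0 = (sigma_w + rho_w u0 v0 / (gamma_w + v0)) / mu_w (from the IL-2
# equation) into the steady effector equation gives a residual f(v0) whose
# roots in (0,1) are the feasible coexistence states. Clearing denominators
# turns f into a quintic polynomial; both routes are implemented and used as
# mutual cross-checks.

.stab_tol <- 1e-10

#' Scalar coexistence residual
#'
#' The steady effector-equation residual as a function of tumour density
#' `v0`, with `u0` and `w0` eliminated through their closed forms. Vectorised
#' over `v0`.
#'
#' @param v0 numeric vector of candidate tumour densities.
#' @param params a [nondim_params()] object.
#' @return Residual values, same length as `v0`.
#' @export
coexistence_residual <- function(v0, params) {
  with(params, {
    u0 <- (gamma_v + v0) * (1 - v0)
    w0 <- (sigma_w + rho_w * u0 * v0 / (gamma_w + v0)) / mu_w
    alpha * v0 - mu_u * u0 + rho_u * u0 * w0 / (1 + w0) + sigma_u
  })
}

# polynomial helpers (coefficients ascending in degree)
.poly_mul <- function(a, b) {
  r <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a))
    r[i:(i + length(b) - 1L)] <- r[i:(i + length(b) - 1L)] + a[i] * b
  r
}
.poly_add <- function(a, b) {
  n <- max(length(a), length(b))
  c(a, numeric(n - length(a))) + c(b, numeric(n - length(b)))
}

#' Quintic polynomial for coexistence states
#'
#' Coefficients (ascending, constant first) of the degree-5 polynomial in
#' `v0` obtained by clearing denominators in [coexistence_residual()]. Its
#' constant term has the closed form
#' \eqn{a_0 = \gamma_w(\gamma_v \rho_u \sigma_w +
#' (\mu_w + \sigma_w)(\sigma_u - \gamma_v \mu_u))}, which vanishes exactly on
#' the transcritical curve where a coexistence branch crosses the cancer-free
#' state.
#'
#' @param params a [nondim_params()] object.
#' @return Numeric vector of 6 coefficients, ascending; attribute `a0_closed`
#'   carries the closed-form constant term.
#' @export
coexistence_polynomial <- function(params) {
  with(params, {
    u <- c(gamma_v, 1 - gamma_v, -1)                 # (gamma_v+v)(1-v)
    base <- .poly_add(c(0, alpha), -mu_u * u)        # alpha v - mu_u u
    Q1 <- c(gamma_w, 1)                              # gamma_w + v
    N0 <- rho_w * .poly_mul(c(0, 1), u)              # rho_w v u
    Q0 <- .poly_add(mu_w * Q1, N0)                   # Dw + rho_w v u
    P <- .poly_add(.poly_mul(base, Q0), rho_u * .poly_mul(u, N0))
    P <- .poly_add(P, sigma_u * Q0)
    P <- .poly_add(P, sigma_w * .poly_add(.poly_mul(base, Q1),
                                          rho_u * .poly_mul(u, Q1)))
    P <- .poly_add(P, (sigma_u * sigma_w) * Q1)
    a0 <- gamma_w * (gamma_v * rho_u * sigma_w +
                       (mu_w + sigma_w) * (sigma_u - gamma_v * mu_u))
    structure(P, a0_closed = a0)
  })
}

.equilibrium <- function(state, kind, params) {
  J <- reaction_jacobian(state, params)
  ev <- eigen(J, only.values = TRUE)$values
  re <- Re(ev)
  structure(list(state = c(u = unname(state[1]), v = unname(state[2]),
                           w = unname(state[3])),
                 kind = kind, eigenvalues = ev,
                 stable = all(re < -.stab_tol),
                 marginal = any(abs(re) <= .stab_tol)),
            class = "equilibrium")
}

#' @export
print.equilibrium <- function(x, ...) {
  cat(sprintf("%s equilibrium (u,v,w) = (%.6g, %.6g, %.6g); %s\n",
              x$kind, x$state[1], x$state[2], x$state[3],
              if (x$stable) "stable" else "unstable"))
  invisible(x)
}

#' Cancer-free equilibrium
#'
#' The unique steady state with zero tumour density:
#' \eqn{(u_0, 0, w_0)} with
#' \eqn{u_0 = \sigma_u(\mu_w+\sigma_w) / (\mu_u(\mu_w+\sigma_w) -
#' \rho_u\sigma_w)} and \eqn{w_0 = \sigma_w/\mu_w}. Feasible only while
#' \eqn{\mu_u(\mu_w+\sigma_w) > \rho_u\sigma_w}.
#'
#' @param params a [nondim_params()] object.
#' @return An `equilibrium` object with `kind = "cancer_free"`.
#' @export
cancer_free_equilibrium <- function(params) {
  den <- with(params, mu_u * (mu_w + sigma_w) - rho_u * sigma_w)
  if (den <= 0)
    stop("cancer-free state infeasible: mu_u(mu_w+sigma_w) <= rho_u sigma_w")
  u0 <- with(params, sigma_u * (mu_w + sigma_w)) / den
  w0 <- with(params, sigma_w / mu_w)
  .equilibrium(c(u0, 0, w0), "cancer_free", params)
}

#' Closed-form eigenvalues at the cancer-free state
#'
#' Returns \eqn{(\lambda_1, \lambda_2, \lambda_3)}:
#' \eqn{\lambda_1 = 1 - u_0/\gamma_v} (tumour invasion rate),
#' \eqn{\lambda_2 = (\rho_u\sigma_w - \mu_u(\mu_w+\sigma_w))/(\mu_w+\sigma_w)}
#' and \eqn{\lambda_3 = -\mu_w}.
#'
#' @param params a [nondim_params()] object.
#' @return Numeric length-3 vector.
#' @export
cancer_free_eigenvalues <- function(params) {
  den <- with(params, mu_u * (mu_w + sigma_w) - rho_u * sigma_w)
  if (den <= 0)
    stop("cancer-free state infeasible: mu_u(mu_w+sigma_w) <= rho_u sigma_w")
  with(params, c(
    1 - sigma_u * (mu_w + sigma_w) / (gamma_v * den),
    (rho_u * sigma_w - mu_u * (mu_w + sigma_w)) / (mu_w + sigma_w),
    -mu_w))
}

#' Complete a coexistence tumour density to the full state
#'
#' @param v0 tumour density in (0,1) (vectorised).
#' @param params a [nondim_params()] object.
#' @return Matrix with columns `u`, `v`, `w`.
#' @export
complete_coexistence_state <- function(v0, params) {
  with(params, {
    u0 <- (gamma_v + v0) * (1 - v0)
    w0 <- (sigma_w + rho_w * u0 * v0 / (gamma_w + v0)) / mu_w
    cbind(u = u0, v = v0, w = w0)
  })
}

#' Coexistence equilibria
#'
#' All steady states with tumour density strictly inside (0,1). The default
#' route evaluates [coexistence_residual()] on a dense grid of `v0`, brackets
#' sign changes and polishes each root by bisection ([uniroot()]); the
#' `"quintic"` route takes the real roots of [coexistence_polynomial()]
#' instead. Roots closer than `merge_tol` are merged (folds produce
#' near-double roots).
#'
#' @param params a [nondim_params()] object.
#' @param method root-finding route, `"scan"` (default) or `"quintic"`.
#' @param n_grid grid resolution of the scan route.
#' @param merge_tol roots closer than this in `v0` are merged.
#' @return A list of `equilibrium` objects (possibly empty), ordered by
#'   increasing tumour density.
#' @export
coexistence_equilibria <- function(params, method = c("scan", "quintic"),
                                   n_grid = 2001, merge_tol = 1e-8) {
  method <- match.arg(method)
  v0 <- coexistence_roots(params, method, n_grid, merge_tol)
  lapply(v0, function(v) {
    s <- complete_coexistence_state(v, params)
    .equilibrium(c(s[1, "u"], v, s[1, "w"]), "coexistence", params)
  })
}

#' Coexistence tumour densities (roots only)
#'
#' @inheritParams coexistence_equilibria
#' @return Sorted numeric vector of roots in (0,1).
#' @export
coexistence_roots <- function(params, method = c("scan", "quintic"),
                              n_grid = 2001, merge_tol = 1e-8) {
  method <- match.arg(method)
  eps <- 1e-12
  if (method == "scan") {
    vg <- seq(eps, 1 - eps, length.out = n_grid)
    fv <- coexistence_residual(vg, params)
    idx <- which(diff(sign(fv)) != 0)
    roots <- vapply(idx, function(j)
      uniroot(coexistence_residual, c(vg[j], vg[j + 1]), params = params,
              tol = .Machine$double.eps^0.75)$root, numeric(1))
  } else {
    P <- coexistence_polynomial(params)
    r <- polyroot(P)
    roots <- Re(r[abs(Im(r)) < 1e-7 * (1 + abs(Re(r))) &
                    Re(r) > eps & Re(r) < 1 - eps])
    # Newton polish on the scalar residual
    for (k in seq_len(3)) {
      if (!length(roots)) break
      f <- coexistence_residual(roots, params)
      df <- (coexistence_residual(roots + 1e-7, params) -
               coexistence_residual(roots - 1e-7, params)) / 2e-7
      roots <- pmin(pmax(roots - f / df, eps), 1 - eps)
    }
    roots <- roots[abs(coexistence_residual(roots, params)) < 1e-8]
  }
  roots <- sort(roots)
  if (length(roots) > 1)
    roots <- roots[c(TRUE, diff(roots) > merge_tol)]
  roots
}

#' Transcritical treatment threshold
#'
#' The effector-input level \eqn{\sigma_u^*} at which the constant term of
#' the coexistence quintic vanishes, i.e. where a coexistence branch crosses
#' the cancer-free state (\eqn{\lambda_1 = 0}):
#' \eqn{\sigma_u^* = \gamma_v\mu_u - \gamma_v\rho_u\sigma_w/(\mu_w+\sigma_w)}.
#'
#' @param params a [nondim_params()] object; its `sigma_u` is ignored.
#' @return The critical effector input (scalar).
#' @export
transcritical_sigma_u <- function(params) {
  with(params, {
    if (mu_w + sigma_w <= 0) stop("mu_w + sigma_w must be positive")
    gamma_v * mu_u - gamma_v * rho_u * sigma_w / (mu_w + sigma_w)
  })
}

# Vectorised Routh-Hurwitz stability of coexistence states: for the cubic
# characteristic polynomial lambda^3 + c2 lambda^2 + c1 lambda + c0, the
# state is stable iff c2 > 0, c0 > 0 and c2 c1 > c0.
.coex_stable_bulk <- function(v0, sigma_u, sigma_w, params) {
  with(params, {
    u0 <- (gamma_v + v0) * (1 - v0)
    w0 <- (sigma_w + rho_w * u0 * v0 / (gamma_w + v0)) / mu_w
    J11 <- rho_u * w0 / (w0 + 1) - mu_u
    J12 <- alpha
    J13 <- rho_u * u0 / (w0 + 1)^2
    J21 <- -v0 / (gamma_v + v0)
    J22 <- u0 * v0 / (gamma_v + v0)^2 - u0 / (gamma_v + v0) - 2 * v0 + 1
    J31 <- rho_w * v0 / (gamma_w + v0)
    J32 <- rho_w * u0 * gamma_w / (gamma_w + v0)^2
    J33 <- -mu_w
    c2 <- -(J11 + J22 + J33)
    c1 <- J11 * J22 + J11 * J33 + J22 * J33 - J12 * J21 - J13 * J31
    c0 <- -(J11 * J22 * J33 - J11 * 0 * J32 - J12 * J21 * J33 +
              J12 * 0 * J31 + J13 * J21 * J32 - J13 * J22 * J31)
    c2 > .stab_tol & c0 > .stab_tol & (c2 * c1 - c0) > .stab_tol
  })
}

.region_levels <- c("CF_only", "one_coex", "two_coex", "CF_and_coex",
                    "none_stable")

#' Classify the stable homogeneous steady-state set
#'
#' Labels a parameter point by which homogeneous equilibria are linearly
#' stable: only the cancer-free state (`CF_only`), one or two coexistence
#' states and no stable cancer-free state (`one_coex`, `two_coex`), both a
#' stable cancer-free and a stable coexistence state (`CF_and_coex`), or no
#' stable equilibrium at all (`none_stable`, the oscillatory regime).
#'
#' @param params a [nondim_params()] object.
#' @return A single character label.
#' @export
classify_homogeneous <- function(params) {
  cf_stable <- FALSE
  den <- with(params, mu_u * (mu_w + sigma_w) - rho_u * sigma_w)
  if (den > 0)
    cf_stable <- all(cancer_free_eigenvalues(params) < -.stab_tol)
  v0 <- coexistence_roots(params, method = "quintic")
  n_coex <- if (length(v0))
    sum(.coex_stable_bulk(v0, params$sigma_u, params$sigma_w, params))
  else 0L
  if (cf_stable && n_coex > 0) return("CF_and_coex")
  if (cf_stable) return("CF_only")
  if (n_coex >= 2) return("two_coex")
  if (n_coex == 1) return("one_coex")
  "none_stable"
}

#' Stability-region scan over the treatment plane
#'
#' Classifies the stable homogeneous steady-state set on a grid of the two
#' treatment inputs at fixed immune response `alpha`.
#'
#' @param params a [nondim_params()] object supplying all non-treatment
#'   parameters (and `alpha`).
#' @param sigma_u,sigma_w ascending numeric grids.
#' @return A `character` matrix of region labels with `length(sigma_u)` rows
#'   and `length(sigma_w)` columns; attributes `sigma_u`, `sigma_w`, `alpha`.
#' @export
scan_stability_plane <- function(params,
                                 sigma_u = seq(0, 0.05, length.out = 201),
                                 sigma_w = seq(0, 20, length.out = 201)) {
  stopifnot(!is.unsorted(sigma_u), !is.unsorted(sigma_w))
  lab <- matrix(NA_character_, length(sigma_u), length(sigma_w))
  for (j in seq_along(sigma_w)) {
    for (i in seq_along(sigma_u)) {
      p <- params
      p$sigma_u <- sigma_u[i]; p$sigma_w <- sigma_w[j]
      lab[i, j] <- classify_homogeneous(p)
    }
  }
  structure(lab, sigma_u = sigma_u, sigma_w = sigma_w, alpha = params$alpha)
}

#' Upper immune-response bound for dual bistability
#'
#' Locates, by bisection in `alpha`, the largest immune-response strength at
#' which the treatment plane still contains both bistable region types: a
#' cell where the cancer-free and a coexistence state are simultaneously
#' stable (`CF_and_coex`) and a cell with two stable coexistence states
#' (`two_coex`).
#'
#' @param params baseline [nondim_params()] object (its `alpha` is ignored).
#' @param sigma_u,sigma_w scan grids, as in [scan_stability_plane()].
#' @param alpha_range bracketing interval for the bound.
#' @param tol bisection tolerance on `alpha`.
#' @return The critical `alpha` (scalar).
#' @export
bistability_alpha_bound <- function(params,
                                    sigma_u = seq(0, 0.05, length.out = 201),
                                    sigma_w = seq(0, 20, length.out = 201),
                                    alpha_range = c(0.05, 0.12),
                                    tol = 1e-3) {
  both <- function(alpha) {
    p <- params; p$alpha <- alpha
    lab <- scan_stability_plane(p, sigma_u, sigma_w)
    any(lab == "CF_and_coex") && any(lab == "two_coex")
  }
  lo <- alpha_range[1]; hi <- alpha_range[2]
  if (!both(lo)) stop("lower alpha bracket has no dual bistability")
  if (both(hi)) stop("upper alpha bracket still has dual bistability")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (both(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
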