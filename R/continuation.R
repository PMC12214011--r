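# Steady states of the discretised PDE and pseudo-arclength continuation.
#
# The discretised steady-state problem is F(fields; p) = 0 where F applies
# the Neumann Laplacian (sparse, from build_laplacian()) plus the reaction
# terms, and p is one of the treatment inputs. Branches are traced with a
# secant-predictor / Newton-corrector pseudo-arclength scheme able to round
# folds; the homogeneous branch is also available in closed form because the
# steady equations are linear in either treatment input.

#' Steady-state residual on a domain
#'
#' @param fields `N` x 3 matrix of nodal values (columns u, v, w).
#' @param params a [nondim_params()] object.
#' @param dom a `domain_nd` object.
#' @param Lap optional precomputed [build_laplacian()] operator.
#' @return `N` x 3 matrix of residuals.
#' @export
steady_residual <- function(fields, params, dom, Lap = NULL) {
  stopifnot(is.matrix(fields), nrow(fields) == dom$N, ncol(fields) == 3)
  if (is.null(Lap)) Lap <- build_laplacian(dom)
  u <- fields[, 1]; v <- fields[, 2]; w <- fields[, 3]
  with(params, cbind(
    delta_u * as.numeric(Lap %*% u) + alpha * v - mu_u * u +
      rho_u * u * w / (1 + w) + sigma_u,
    as.numeric(Lap %*% v) + v * (1 - v) - u * v / (gamma_v + v),
    delta_w * as.numeric(Lap %*% w) + rho_w * u * v / (gamma_w + v) -
      mu_w * w + sigma_w))
}

# sparse 3N x 3N Jacobian of the steady residual
steady_jacobian <- function(fields, params, dom, Lap = NULL) {
  if (is.null(Lap)) Lap <- build_laplacian(dom)
  u <- fields[, 1]; v <- fields[, 2]; w <- fields[, 3]
  with(params, {
    J11 <- rho_u * w / (w + 1) - mu_u
    J12 <- rep(alpha, dom$N)
    J13 <- rho_u * u / (w + 1)^2
    J21 <- -v / (gamma_v + v)
    J22 <- u * v / (gamma_v + v)^2 - u / (gamma_v + v) - 2 * v + 1
    J31 <- rho_w * v / (gamma_w + v)
    J32 <- rho_w * u * gamma_w / (gamma_w + v)^2
    J33 <- rep(-mu_w, dom$N)
    D <- Matrix::Diagonal
    rbind(
      cbind(delta_u * Lap + D(x = J11), D(x = J12), D(x = J13)),
      cbind(D(x = J21), Lap + D(x = J22),
            Matrix::Matrix(0, dom$N, dom$N, sparse = TRUE)),
      cbind(D(x = J31), D(x = J32), delta_w * Lap + D(x = J33)))
  })
}

# derivative of the steady residual w.r.t. a treatment input
.dF_dp <- function(param_name, N) {
  if (param_name == "sigma_u") c(rep(1, N), numeric(2 * N))
  else c(numeric(2 * N), rep(1, N))
}

#' Newton solve for a steady state
#'
#' @inheritParams steady_residual
#' @param tol convergence tolerance on the max-norm residual.
#' @param maxit maximum Newton iterations.
#' @return A list with `fields`, `resid` (final max-norm) and `converged`.
#' @export
newton_steady <- function(fields, params, dom, Lap = NULL, tol = 1e-10,
                          maxit = 30) {
  if (is.null(Lap)) Lap <- build_laplacian(dom)
  x <- c(fields)
  for (it in seq_len(maxit)) {
    f <- matrix(x, dom$N, 3)
    R <- c(steady_residual(f, params, dom, Lap))
    if (max(abs(R)) < tol)
      return(list(fields = matrix(x, dom$N, 3), resid = max(abs(R)),
                  converged = TRUE, iters = it - 1L))
    J <- steady_jacobian(f, params, dom, Lap)
    dx <- tryCatch(as.numeric(Matrix::solve(J, -R)),
                   error = function(e) NULL)
    if (is.null(dx) || !all(is.finite(dx))) break
    x <- x + dx
  }
  list(fields = matrix(x, dom$N, 3),
       resid = max(abs(c(steady_residual(matrix(x, dom$N, 3), params, dom,
                                         Lap)))),
       converged = FALSE, iters = maxit)
}

# leading eigenvalues (largest real part) of the discretised Jacobian
.leading_eigs <- function(fields, params, dom, Lap, n_lead = 6) {
  J <- steady_jacobian(fields, params, dom, Lap)
  ev <- eigen(as.matrix(J), only.values = TRUE)$values
  ev[order(-Re(ev))][seq_len(min(n_lead, length(ev)))]
}

#' Domain L1 norm and mean of the tumour field
#'
#' Trapezoid-rule integral of `v` over the domain, plus the nodal mean.
#'
#' @param fields `N` x 3 matrix.
#' @param dom a `domain_nd` object.
#' @return Named numeric vector `c(l1, mean)`.
#' @export
v_norm <- function(fields, dom) {
  v <- fields[, 2]
  if (dom$dim == 1L) {
    wts <- rep(dom$h, dom$N); wts[c(1, dom$N)] <- dom$h / 2
  } else {
    wts <- rep(dom$h^2, dom$N)
  }
  c(l1 = sum(abs(v) * wts), mean = mean(v))
}

#' Pseudo-arclength continuation of a steady-state branch
#'
#' Traces the solution branch through `(fields, p)` space with a secant
#' predictor and a Newton corrector on the arclength-augmented system,
#' rounding folds. Folds are tagged at parameter-direction reversals and
#' their location refined by a parabolic fit of the parameter against
#' arclength across the reversal.
#'
#' @param fields converged seed fields (`N` x 3).
#' @param params a [nondim_params()] object holding the seed parameter value.
#' @param dom a `domain_nd` object.
#' @param param_name continuation parameter, `"sigma_u"` or `"sigma_w"`.
#' @param direction initial parameter direction, +1 or -1.
#' @param n_steps point budget.
#' @param ds0,ds_min,ds_max initial/min/max arclength step.
#' @param p_range stop when the parameter leaves this interval.
#' @param stability compute leading eigenvalues at each accepted point
#'   (dense; expensive for fine meshes).
#' @param tol Newton tolerance.
#' @param seed2 optional second point (list with `fields`, `parameter`) used
#'   as the initial secant instead of a parameter step; use this when
#'   starting from a [switch_branch()] seed, whose branch direction is along
#'   the pattern amplitude rather than the parameter.
#' @return A `branch` object: data frame `points` (parameter, `l1` and mean
#'   tumour norms, `stable`, `tag`), list `fields` of accepted states, the
#'   refined `folds` (parameter values), and bookkeeping.
#' @export
continue_branch <- function(fields, params, dom, param_name = "sigma_w",
                            direction = -1, n_steps = 200, ds0 = 1e-2,
                            ds_min = 1e-6, ds_max = 0.1,
                            p_range = c(-2, 25), stability = FALSE,
                            tol = 1e-9, seed2 = NULL) {
  Lap <- build_laplacian(dom)
  dfp <- .dF_dp(param_name, dom$N)
  p0 <- params[[param_name]]
  # weight the parameter like a field component in the arclength metric
  corrector <- function(x_pred, tau, ds, x_base) {
    x <- x_pred
    for (it in seq_len(12)) {
      f <- matrix(x[-length(x)], dom$N, 3)
      pp <- params; pp[[param_name]] <- x[length(x)]
      R <- c(steady_residual(f, pp, dom, Lap))
      g <- sum(tau * (x - x_base)) - ds
      if (max(abs(R)) < tol && abs(g) < tol * 10)
        return(list(x = x, ok = TRUE, iters = it))
      J <- steady_jacobian(f, pp, dom, Lap)
      A <- rbind(cbind(J, dfp), tau)
      dx <- tryCatch(as.numeric(Matrix::solve(A, -c(R, g))),
                     error = function(e) NULL)
      if (is.null(dx) || !all(is.finite(dx))) return(list(ok = FALSE))
      x <- x + dx
    }
    list(ok = FALSE)
  }
  # converge the seed
  ns <- newton_steady(fields, params, dom, Lap, tol = tol)
  if (!ns$converged) stop("seed state did not converge")
  x0 <- c(c(ns$fields), p0)
  ds <- ds0
  if (!is.null(seed2)) {
    # explicit second point (e.g. from branch switching at a bifurcation,
    # where the branch direction is along the pattern amplitude)
    pp <- params; pp[[param_name]] <- seed2$parameter
    ns2 <- newton_steady(seed2$fields, pp, dom, Lap, tol = tol)
    if (!ns2$converged) stop("second seed did not converge")
    x1 <- c(c(ns2$fields), seed2$parameter)
  } else {
    # second point: small parameter step at fixed fields, Newton in fields
    pp <- params; pp[[param_name]] <- p0 + direction * ds
    ns2 <- newton_steady(ns$fields, pp, dom, Lap, tol = tol)
    while (!ns2$converged && ds > ds_min) {
      ds <- ds / 4
      pp[[param_name]] <- p0 + direction * ds
      ns2 <- newton_steady(ns$fields, pp, dom, Lap, tol = tol)
    }
    if (!ns2$converged) stop("could not take an initial parameter step")
    x1 <- c(c(ns2$fields), pp[[param_name]])
  }

  xs <- list(x0, x1)
  accept <- function(x) {
    f <- matrix(x[-length(x)], dom$N, 3)
    vn <- v_norm(f, dom)
    stab <- NA
    if (stability) {
      ppx <- params; ppx[[param_name]] <- x[length(x)]
      lead <- .leading_eigs(f, ppx, dom, Lap)
      stab <- all(Re(lead) < -1e-8)
    }
    data.frame(parameter = x[length(x)], l1 = vn["l1"], mean = vn["mean"],
               stable = stab, tag = "regular", stringsAsFactors = FALSE)
  }
  pts <- rbind(accept(x0), accept(x1))
  folds <- numeric(0)
  k <- 2
  while (k < n_steps) {
    n <- length(xs)
    tau <- xs[[n]] - xs[[n - 1]]
    tau <- tau / sqrt(sum(tau^2))
    res <- corrector(xs[[n]] + ds * tau, tau, ds, xs[[n]])
    if (!res$ok) {
      ds <- ds / 2
      if (ds < ds_min) break
      next
    }
    xs[[n + 1]] <- res$x
    pts <- rbind(pts, accept(res$x))
    k <- k + 1
    if (res$iters <= 3 && ds < ds_max) ds <- min(ds * 1.4, ds_max)
    p_new <- res$x[length(res$x)]
    if (p_new < p_range[1] || p_new > p_range[2]) break
  }
  # fold detection: local extrema of the parameter along the branch
  p_seq <- pts$parameter
  if (length(p_seq) >= 3) {
    dp <- diff(p_seq)
    rev_idx <- which(dp[-1] * dp[-length(dp)] < 0) + 1L
    for (i in rev_idx) {
      pts$tag[i] <- "fold"
      # parabolic refinement of p against arclength
      s <- c(-1, 0, 1)
      pv <- p_seq[(i - 1):(i + 1)]
      den <- pv[1] - 2 * pv[2] + pv[3]
      folds <- c(folds, if (abs(den) > 0)
        pv[2] - (pv[3] - pv[1])^2 / (8 * den) else pv[2])
    }
  }
  structure(list(points = pts, fields = xs, folds = folds,
                 param_name = param_name, dom = dom, params = params),
            class = "branch")
}

#' @export
print.branch <- function(x, ...) {
  cat(sprintf("branch in %s: %d points, parameter in [%.5g, %.5g]",
              x$param_name, nrow(x$points), min(x$points$parameter),
              max(x$points$parameter)))
  if (length(x$folds))
    cat(sprintf("; folds at %s", paste(signif(x$folds, 6), collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Homogeneous branch in closed form
#'
#' Because the steady well-mixed equations are linear in either treatment
#' input, the homogeneous coexistence branch can be parameterised by the
#' tumour density `v0`: for each `v0` the input value putting `(u0, v0, w0)`
#' on the branch is solved for exactly. Stability (3x3 eigenvalues) and the
#' Turing test are evaluated at each point.
#'
#' @param params a [nondim_params()] object (the varied input is ignored).
#' @param param_name `"sigma_u"` or `"sigma_w"`.
#' @param v0 tumour densities parameterising the branch.
#' @return Data frame with `v0`, `parameter`, `u0`, `w0`, `stable`,
#'   `turing_unstable`.
#' @export
homogeneous_branch <- function(params, param_name = "sigma_u",
                               v0 = seq(1e-4, 1 - 1e-4, length.out = 400)) {
  with(params, {
    u0 <- (gamma_v + v0) * (1 - v0)
    g <- rho_w * u0 * v0 / (gamma_w + v0)
    if (param_name == "sigma_u") {
      w0 <- (sigma_w + g) / mu_w
      par <- -(alpha * v0 - mu_u * u0 + rho_u * u0 * w0 / (1 + w0))
    } else {
      base <- alpha * v0 - mu_u * u0 + sigma_u
      par <- -(base * (mu_w + g) + rho_u * u0 * g) / (base + rho_u * u0)
      w0 <- (par + g) / mu_w
    }
    out <- data.frame(v0 = v0, parameter = par, u0 = u0, w0 = w0,
                      stable = NA, turing_unstable = NA)
    for (i in seq_along(v0)) {
      p <- params; p[[param_name]] <- par[i]
      eq <- .equilibrium(c(u0[i], v0[i], w0[i]), "coexistence", p)
      out$stable[i] <- eq$stable
      out$turing_unstable[i] <- turing_test(p, eq)$unstable
    }
    out
  })
}

#' Hopf point of the homogeneous coexistence branch
#'
#' Locates, by bisection on the real part of the complex eigenvalue pair of
#' the 3x3 kinetics Jacobian along the (upper) coexistence branch, the
#' treatment input at which the branch undergoes its Hopf bifurcation.
#'
#' @param params a [nondim_params()] object (fixing all other parameters).
#' @param param_name the varied input (default `"sigma_u"`).
#' @param bracket interval known to contain exactly one crossing.
#' @param tol bisection tolerance on the parameter.
#' @return The Hopf parameter value.
#' @export
hopf_point <- function(params, param_name = "sigma_u",
                       bracket = c(0.015, 0.022), tol = 1e-13) {
  track_v <- NULL
  g <- function(p_val) {
    p <- params; p[[param_name]] <- p_val
    v0 <- coexistence_roots(p, method = "quintic")
    if (!length(v0)) return(NA_real_)
    v_sel <- if (is.null(track_v)) max(v0) else v0[which.min(abs(v0 - track_v))]
    track_v <<- v_sel
    s <- complete_coexistence_state(v_sel, p)
    ev <- eigen(reaction_jacobian(s[1, ], p), only.values = TRUE)$values
    cc <- ev[abs(Im(ev)) > 1e-12]
    if (!length(cc)) return(-1)
    max(Re(cc))
  }
  lo <- bracket[1]; hi <- bracket[2]
  glo <- g(lo); ghi <- g(hi)
  if (is.na(glo) || is.na(ghi) || glo * ghi > 0)
    stop("bracket does not contain a single Hopf crossing")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    gm <- g(mid)
    if (gm * glo <= 0) hi <- mid else { lo <- mid; glo <- gm }
  }
  (lo + hi) / 2
}

#' Obtain a patterned steady state
#'
#' Produces a converged spatially patterned steady state at fixed
#' parameters: perturbs the given homogeneous equilibrium (seeded noise or a
#' single cosine mode), integrates the PDE until the pattern saturates, and
#' polishes with Newton.
#'
#' @param params a [nondim_params()] object (must be Turing-unstable at
#'   `eq` for a pattern to develop).
#' @param dom a 1D `domain_nd`.
#' @param eq homogeneous `equilibrium` to perturb.
#' @param mode if non-`NULL`, perturb with `amp * cos(mode * pi * x / L)`
#'   in every species instead of noise.
#' @param amp perturbation amplitude.
#' @param seed RNG seed for the noise route.
#' @param t_settle integration horizon before polishing.
#' @return A list as from [newton_steady()].
#' @export
find_patterned_state <- function(params, dom, eq, mode = NULL, amp = 0.1,
                                 seed = 1, t_settle = 400) {
  if (is.null(mode)) {
    ic <- perturbed_ic(eq, perturbation_spec(eta = amp, seed = seed), dom)
  } else {
    shape <- cos(mode * pi * dom$x / dom$L)
    ic <- matrix(rep(eq$state, each = dom$N), dom$N, 3) *
      (1 + amp * shape)
    ic[ic < 0] <- 0
  }
  proto <- make_protocol("constant", sigma_u = params$sigma_u,
                         sigma_w = params$sigma_w, T_final = t_settle)
  traj <- simulate_model(ic, params, proto, dom,
                         times = seq(0, t_settle, length.out = 11),
                         atol = 1e-9, rtol = 1e-9)
  final <- traj$fields[, , dim(traj$fields)[3]]
  newton_steady(final, params, dom)
}

#' Finite-domain Turing onset along the homogeneous branch
#'
#' On an interval of length `L` with Neumann conditions the admissible
#' wavenumbers are `k = n pi / L`. This locates, by bisection in the
#' treatment input, the onset at which the leading growth rate over the
#' first `n_max` modes crosses zero for the tracked (upper) coexistence
#' state, and reports the critical mode.
#'
#' @param params a [nondim_params()] object.
#' @param dom a 1D `domain_nd`.
#' @param param_name varied input.
#' @param bracket interval containing one onset.
#' @param n_max number of modes scanned.
#' @param tol bisection tolerance.
#' @return List with `parameter`, `mode`, `k2` and the homogeneous
#'   `equilibrium` at onset.
#' @export
turing_onset <- function(params, dom, param_name = "sigma_u",
                         bracket = c(0.014, 0.0195), n_max = 12,
                         tol = 1e-10) {
  k2s <- (seq_len(n_max) * pi / dom$L)^2
  track_v <- NULL
  gmax <- function(p_val) {
    p <- params; p[[param_name]] <- p_val
    v0 <- coexistence_roots(p, method = "quintic")
    if (!length(v0)) return(NA_real_)
    v_sel <- if (is.null(track_v)) max(v0) else
      v0[which.min(abs(v0 - track_v))]
    track_v <<- v_sel
    s <- complete_coexistence_state(v_sel, p)
    J <- reaction_jacobian(s[1, ], p)
    max(vapply(k2s, function(k2)
      growth_rates(J, p$delta_u, p$delta_w, k2)$max_re, numeric(1)))
  }
  lo <- bracket[1]; hi <- bracket[2]
  glo <- gmax(lo)
  if (glo * gmax(hi) > 0) stop("bracket does not contain a Turing onset")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    gm <- gmax(mid)
    if (gm * glo <= 0) hi <- mid else { lo <- mid; glo <- gm }
  }
  p_star <- (lo + hi) / 2
  p <- params; p[[param_name]] <- p_star
  v0 <- coexistence_roots(p, method = "quintic")
  v_sel <- v0[which.min(abs(v0 - track_v))]
  s <- complete_coexistence_state(v_sel, p)
  J <- reaction_jacobian(s[1, ], p)
  rates <- vapply(k2s, function(k2)
    growth_rates(J, p$delta_u, p$delta_w, k2)$max_re, numeric(1))
  n_star <- which.max(rates)
  list(parameter = p_star, mode = n_star, k2 = k2s[n_star],
       equilibrium = .equilibrium(s[1, ], "coexistence", p))
}

#' Branch switching at a Turing bifurcation
#'
#' Produces a converged seed on the patterned branch bifurcating from the
#' homogeneous state at a finite-domain Turing point: the homogeneous state
#' is perturbed along `cos(n pi x / L)` times the critical eigenvector of
#' the mode matrix, and a Newton corrector on the parameter-augmented system
#' with the perturbation amplitude pinned converges onto the bifurcating
#' branch (the parameter adjusts to the branch's location at that
#' amplitude). Seeding with mode `-n` gives the spatially reflected branch.
#'
#' @param onset result of [turing_onset()] (or a compatible list).
#' @param params a [nondim_params()] object at the onset parameter.
#' @param dom a 1D `domain_nd`.
#' @param param_name continuation parameter.
#' @param mode signed mode number (sign flips the phase).
#' @param amp pinned perturbation amplitude.
#' @return A list with converged `fields`, adjusted `parameter`, and
#'   `converged`.
#' @export
switch_branch <- function(onset, params, dom, param_name = "sigma_u",
                          mode = onset$mode, amp = 0.05) {
  Lap <- build_laplacian(dom)
  p <- params; p[[param_name]] <- onset$parameter
  eqs <- onset$equilibrium$state
  J <- reaction_jacobian(eqs, p)
  Mk <- J - diag(c(p$delta_u, 1, p$delta_w)) * onset$k2
  ed <- eigen(Mk)
  icrit <- which.min(abs(Re(ed$values)))
  phi <- Re(ed$vectors[, icrit])
  phi <- phi / sqrt(sum(phi^2)) * sign(phi[2] + 1e-300)
  shape <- cos(abs(mode) * pi * dom$x / dom$L) * sign(mode)
  dirvec <- c(outer(shape, phi)) # N x 3 layout, stacked
  dirvec <- dirvec / sqrt(sum(dirvec^2))
  base <- c(rep(eqs[1], dom$N), rep(eqs[2], dom$N), rep(eqs[3], dom$N))
  x <- c(base + amp * dirvec, onset$parameter)
  dfp <- .dF_dp(param_name, dom$N)
  for (it in seq_len(30)) {
    f <- matrix(x[-length(x)], dom$N, 3)
    pp <- p; pp[[param_name]] <- x[length(x)]
    R <- c(steady_residual(f, pp, dom, Lap))
    g <- sum(dirvec * (x[-length(x)] - base)) - amp
    if (max(abs(R)) < 1e-9 && abs(g) < 1e-8)
      return(list(fields = f, parameter = x[length(x)], converged = TRUE))
    Jx <- steady_jacobian(f, pp, dom, Lap)
    A <- rbind(cbind(Jx, dfp), c(dirvec, 0))
    dx <- tryCatch(as.numeric(Matrix::solve(A, -c(R, g))),
                   error = function(e) NULL)
    if (is.null(dx) || !all(is.finite(dx)))
      return(list(fields = f, parameter = x[length(x)], converged = FALSE))
    x <- x + dx
  }
  list(fields = matrix(x[-length(x)], dom$N, 3),
       parameter = x[length(x)], converged = FALSE)
}

#' Criticality of a pattern-forming bifurcation
#'
#' A Turing bifurcation is subcritical when the bifurcating patterned branch
#' initially extends into the parameter side on which the homogeneous state
#' is still stable (producing bistability and hysteresis), supercritical
#' when it extends into the unstable side.
#'
#' @param branch a `branch` object emanating from the bifurcation.
#' @param p_crit the bifurcation parameter value.
#' @param stable_side sign (+1/-1) of the parameter direction, from
#'   `p_crit`, in which the homogeneous state is stable.
#' @param n_probe number of early branch points used to determine direction.
#' @return `"subcritical"` or `"supercritical"`.
#' @export
classify_criticality <- function(branch, p_crit, stable_side,
                                 n_probe = 10) {
  p <- branch$points$parameter
  if (length(p) < 3) stop("branch too short to classify")
  probe <- p[seq_len(min(n_probe, length(p)))]
  dirn <- sign(mean(probe - p_crit))
  if (dirn == 0) stop("branch direction undetermined")
  if (dirn == sign(stable_side)) "subcritical" else "supercritical"
}
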