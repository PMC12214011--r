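# Stiff method-of-lines simulation of the tumour-immune model.

# (row, column) sparsity pattern of the method-of-lines Jacobian: each
# species couples to its own diffusion stencil plus the local values of the
# other species (u<-v,w; v<-u; w<-u,v)
.mol_sparsity <- function(dom) {
  N <- dom$N
  stencil <- cbind(seq_len(N), seq_len(N))
  for (k in seq_len(ncol(dom$nb)))
    stencil <- rbind(stencil, cbind(seq_len(N), dom$nb[, k]))
  blk <- function(bi, bj, idx) cbind(idx[, 1] + (bi - 1L) * N,
                                     idx[, 2] + (bj - 1L) * N)
  local <- cbind(seq_len(N), seq_len(N))
  inz <- rbind(blk(1, 1, stencil), blk(1, 2, local), blk(1, 3, local),
               blk(2, 1, local), blk(2, 2, stencil),
               blk(3, 1, local), blk(3, 2, local), blk(3, 3, stencil))
  key <- as.numeric(inz[, 2]) * (3 * N + 1) + inz[, 1]
  inz <- inz[!duplicated(key), , drop = FALSE]
  inz[order(inz[, 2], inz[, 1]), , drop = FALSE]
}

#' Simulate the reaction-diffusion model
#'
#' Integrates the method-of-lines discretisation of the model on a
#' [domain_interval()], [domain_square()] or [domain_disc()] with a
#' [make_protocol()] treatment protocol, using a variable-order implicit
#' (BDF-type) integrator: `deSolve::lsodes` with an internally generated
#' sparse Jacobian for spatial problems, `deSolve::lsoda` for the well-mixed
#' (`dom = NULL`) case. Time-dependent inputs `sigma_u(t)`, `sigma_w(t)` and
#' the Dirichlet boundary dose `B_w(t)` are evaluated inside the right-hand
#' side. With `nonlinear_v = TRUE` the linear tumour Laplacian is replaced by
#' the volume-filling flux \eqn{\nabla\cdot((1-v)^2\nabla v)} in conservative
#' form.
#'
#' @param ic initial fields: an `N` x 3 matrix (see [perturbed_ic()]), or a
#'   length-3 state for the well-mixed case.
#' @param params a [nondim_params()] object.
#' @param proto a `protocol` object.
#' @param dom a `domain_nd` object, or `NULL` for the well-mixed ODE model.
#' @param times save times (default 201 points over `[0, T_final]`).
#' @param atol,rtol solver tolerances (default `1e-11`, as used for the
#'   reference runs; coarser values are adequate for the 2D scans).
#' @param nonlinear_v use volume-filling nonlinear tumour diffusion.
#' @param maxsteps maximum internal solver steps between save times.
#' @return A `trajectory` object: list with `times`, `fields` (array
#'   `N` x 3 x `length(times)`, non-negative outputs floored at 0), `dom`,
#'   `proto`, `params`, `solver` diagnostics.
#' @export
simulate_model <- function(ic, params, proto, dom = NULL,
                           times = seq(0, proto$T_final, length.out = 201),
                           atol = 1e-11, rtol = 1e-11, nonlinear_v = FALSE,
                           maxsteps = 1e5) {
  sigma_w_ok <- proto$sigma_w(times)
  if (any(sigma_w_ok < 0) || any(proto$sigma_u(times) < 0))
    stop("simulation requires non-negative treatment inputs")
  kin <- with(params, c(alpha, mu_u, rho_u, mu_w, rho_w, gamma_v, gamma_w))
  afl <- if (is.null(proto$atto_fox_floor)) 0 else proto$atto_fox_floor
  if (is.null(dom)) {
    y0 <- as.numeric(ic)
    stopifnot(length(y0) == 3, all(y0 >= 0))
    rhs <- function(t, y, p) {
      list(reaction_rates(y, params, proto$sigma_u(t), proto$sigma_w(t)) +
             c(0, if (afl > 0 && y[2] < afl) -y[2] else 0, 0))
    }
    out <- deSolve::ode(y0, times, rhs, NULL, method = "lsoda",
                        atol = atol, rtol = rtol, maxsteps = maxsteps)
    fields <- array(t(out[, 2:4]), dim = c(1, 3, nrow(out)))
  } else {
    stopifnot(is.matrix(ic), nrow(ic) == dom$N, ncol(ic) == 3)
    dirichlet <- !is.null(proto$Bw)
    rim <- which(dom$boundary)
    y0 <- c(ic[, 1], ic[, 2], ic[, 3])
    if (dirichlet) y0[2 * dom$N + rim] <- proto$Bw(times[1])
    rhs <- function(t, y, p) {
      list(rhs_core(t, y, dom$nb, dom$nbf, dom$h, dom$dim,
                    params$delta_u, params$delta_w, kin,
                    proto$sigma_u(t), proto$sigma_w(t),
                    dirichlet, rim,
                    if (dirichlet) proto$dBw(t) else 0,
                    nonlinear_v, afl))
    }
    inz <- .mol_sparsity(dom)
    out <- deSolve::ode(y0, times, rhs, NULL, method = "lsodes",
                        sparsetype = "sparseusr", inz = inz,
                        nnz = nrow(inz), lrw = max(8e6, 30 * nrow(inz)),
                        atol = atol, rtol = rtol, maxsteps = maxsteps)
    fields <- array(NA_real_, c(dom$N, 3, nrow(out)))
    for (k in seq_len(nrow(out)))
      fields[, , k] <- matrix(out[k, -1], dom$N, 3)
  }
  if (nrow(out) < length(times))
    warning("integrator stopped early: partial trajectory returned")
  fields[fields < 0 & fields > -1e-8] <- 0
  structure(list(times = out[, 1], fields = fields, dom = dom,
                 proto = proto, params = params,
                 solver = attributes(out)$istate),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d save times in [%g, %g], %d nodes (%s)\n",
              length(x$times), min(x$times), max(x$times),
              dim(x$fields)[1],
              if (is.null(x$dom)) "well-mixed" else x$dom$geometry))
  invisible(x)
}

#' Tumour extinction time
#'
#' First time at which the spatial maximum of the tumour density falls below
#' `threshold`, linearly interpolated between save times; `NA` if the
#' trajectory never crosses. The default threshold `1e-6` corresponds to
#' roughly one cell per unit length at the model's density scale.
#'
#' @param traj a `trajectory` object.
#' @param threshold extinction threshold on the tumour density.
#' @return Extinction time (scalar) or `NA`.
#' @export
extinction_time <- function(traj, threshold = 1e-6) {
  vmax <- apply(traj$fields[, 2, , drop = FALSE], 3, max)
  i <- which(vmax < threshold)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1) return(traj$times[1])
  t0 <- traj$times[i - 1]; t1 <- traj$times[i]
  v0 <- vmax[i - 1]; v1 <- vmax[i]
  t0 + (threshold - v0) * (t1 - t0) / (v1 - v0)
}

#' Spatial-average series and kymograph
#'
#' Per-species means over the active (interior) nodes at each save time,
#' plus, for 1D trajectories, the time-by-space tumour-density array used
#' for kymographs.
#'
#' @param traj a `trajectory` object.
#' @return A list with `means` (data frame: `time`, `u`, `v`, `w`) and
#'   `kymograph` (matrix, rows = times, or `NULL` for 2D / well-mixed runs).
#' @export
summarise_trajectory <- function(traj) {
  means <- data.frame(
    time = traj$times,
    u = apply(traj$fields[, 1, , drop = FALSE], 3, mean),
    v = apply(traj$fields[, 2, , drop = FALSE], 3, mean),
    w = apply(traj$fields[, 3, , drop = FALSE], 3, mean))
  kymo <- NULL
  if (!is.null(traj$dom) && traj$dom$dim == 1L)
    kymo <- t(traj$fields[, 2, ])
  list(means = means, kymograph = kymo)
}

#' Well-mixed trajectory from a coexistence equilibrium
#'
#' Convenience wrapper: integrates the ODE model from the upper stable
#' coexistence equilibrium of the protocol's initial parameter values.
#'
#' @param params a [nondim_params()] object.
#' @param proto a `protocol` object (initial inputs are taken at `t = 0`).
#' @param times save times.
#' @param ... further arguments to [simulate_model()].
#' @return A `trajectory` object.
#' @export
ode_from_coexistence <- function(params, proto,
                                 times = seq(0, proto$T_final,
                                             length.out = 2001), ...) {
  p0 <- params
  p0$sigma_u <- proto$sigma_u(0)
  p0$sigma_w <- proto$sigma_w(0)
  eqs <- coexistence_equilibria(p0)
  stable <- Filter(function(e) e$stable, eqs)
  if (!length(stable)) stop("no stable coexistence equilibrium at t = 0")
  eq <- stable[[which.max(vapply(stable, function(e) e$state["v"],
                                 numeric(1)))]]
  simulate_model(eq$state, params, proto, dom = NULL, times = times, ...)
}
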