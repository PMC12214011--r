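# Treatment protocols and seeded random initial conditions.

#' Heaviside step function
#'
#' With the convention `H(0) = 1/2`. The ramp formulas used in the treatment
#' protocols are continuous at their switch points, so the convention does
#' not affect any protocol value.
#'
#' @param x numeric vector.
#' @return Numeric vector of 0, 1/2, 1.
#' @export
heaviside <- function(x) (sign(x) + 1) / 2

#' Treatment protocols
#'
#' Builds the time-dependent treatment inputs used in the study as closures:
#' \describe{
#'   \item{constant}{fixed `sigma_u`, `sigma_w`.}
#'   \item{linear_ramp}{one input ramped linearly, either as
#'     `from + (to - from) t/T` (give `from`, `to`) or `base + rate t`
#'     (give `base`, `rate`); the other input constant.}
#'   \item{triangular_ramp}{`sigma_w = peak (t/T_ramp H(1/2 - t/T_ramp) +
#'     (1 - t/T_ramp) H(t/T_ramp - 1/2))`, reaching `peak/2` at the midpoint;
#'     with `off_after = TRUE` the whole expression is multiplied by
#'     `H(1 - t/T_ramp)` so treatment switches off after the ramp.}
#'   \item{boundary_ramp}{constant volumetric inputs plus Dirichlet IL-2
#'     dosing `w = B_w(t) = bw_rate t` on the domain rim.}
#' }
#'
#' @param kind protocol kind.
#' @param sigma_u,sigma_w constant input levels (used where not ramped).
#' @param ramp for `linear_ramp`: which input ramps (`"sigma_u"` or
#'   `"sigma_w"`).
#' @param from,to,T_final ramp endpoints over `[0, T_final]`.
#' @param base,rate alternative ramp parametrisation `base + rate t`.
#' @param peak,T_ramp,off_after triangular-ramp parameters.
#' @param bw_rate boundary Dirichlet dosing rate (`B_w(t) = bw_rate t`).
#' @param atto_fox_floor if non-`NULL`, adds the sink `-H(floor - v) v` to
#'   the tumour equation (extinction floor against the Atto-fox artefact;
#'   conventionally `1e-15`).
#' @return A `protocol` object: list of closures `sigma_u(t)`, `sigma_w(t)`,
#'   optional `Bw(t)` and its derivative `dBw(t)`, plus `T_final` and
#'   `atto_fox_floor`.
#' @export
make_protocol <- function(kind = c("constant", "linear_ramp",
                                   "triangular_ramp", "boundary_ramp"),
                          sigma_u = 0, sigma_w = 0, ramp = "sigma_u",
                          from = NULL, to = NULL, T_final = 1e5,
                          base = NULL, rate = NULL,
                          peak = 18, T_ramp = T_final, off_after = FALSE,
                          bw_rate = 0.01, atto_fox_floor = NULL) {
  kind <- match.arg(kind)
  const_fun <- function(val) {
    force(val); function(t) rep_len(val, length(t))
  }
  su <- const_fun(sigma_u)
  sw <- const_fun(sigma_w)
  Bw <- NULL; dBw <- NULL
  if (kind == "linear_ramp") {
    stopifnot(ramp %in% c("sigma_u", "sigma_w"))
    f <- if (!is.null(base)) {
      force(base); force(rate); function(t) base + rate * t
    } else {
      stopifnot(!is.null(from), !is.null(to))
      function(t) from + (to - from) * t / T_final
    }
    if (ramp == "sigma_u") su <- f else sw <- f
  } else if (kind == "triangular_ramp") {
    force(peak); force(T_ramp); force(off_after)
    sw <- function(t) {
      s <- t / T_ramp
      val <- peak * (s * heaviside(0.5 - s) + (1 - s) * heaviside(s - 0.5))
      if (off_after) val <- val * heaviside(1 - s)
      val
    }
  } else if (kind == "boundary_ramp") {
    force(bw_rate)
    Bw <- function(t) bw_rate * t
    dBw <- function(t) rep_len(bw_rate, length(t))
  }
  structure(list(kind = kind, sigma_u = su, sigma_w = sw,
                 Bw = Bw, dBw = dBw, T_final = T_final,
                 atto_fox_floor = atto_fox_floor),
            class = "protocol")
}

#' Atto-fox extinction sink
#'
#' The sink term `-H(floor - v) v` added to the tumour equation to remove
#' biologically meaningless sub-cellular densities: it returns `-v` when
#' `v < floor` and `0` otherwise (vectorised).
#'
#' @param v tumour density (vector).
#' @param floor extinction floor (> 0), conventionally `1e-15`.
#' @return Sink rates, same shape as `v`.
#' @export
atto_fox_term <- function(v, floor = 1e-15) {
  stopifnot(floor > 0)
  -heaviside(floor - v) * v
}

#' Perturbation specification for initial conditions
#'
#' @param eta relative noise amplitude (>= 0; the study default is 0.1).
#' @param seed integer RNG seed (required when `eta > 0`).
#' @param per_species_independent draw an independent noise field for each
#'   species (default) or share one field across species.
#' @return A `perturbation_spec` object.
#' @export
perturbation_spec <- function(eta = 0.1, seed = NULL,
                              per_species_independent = TRUE) {
  stopifnot(eta >= 0)
  if (eta > 0 && is.null(seed))
    stop("a seed is required for stochastic initial conditions")
  structure(list(eta = eta, seed = seed,
                 per_species_independent = per_species_independent),
            class = "perturbation_spec")
}

#' Randomly perturbed homogeneous initial condition
#'
#' Multiplies each species' homogeneous equilibrium value by
#' `1 + eta * xi(x)` with `xi` i.i.d. standard normal per node (fresh field
#' per species unless `per_species_independent = FALSE`); negative values
#' are floored at zero. With `eta = 0` the exact homogeneous state is
#' returned. Identical spec and domain give bit-identical fields.
#'
#' @param eq an `equilibrium` object (see [coexistence_equilibria()]).
#' @param spec a [perturbation_spec()].
#' @param dom a `domain_nd` object.
#' @return An `N` x 3 matrix with columns `u`, `v`, `w`.
#' @export
perturbed_ic <- function(eq, spec, dom) {
  vals <- eq$state
  N <- dom$N
  fields <- matrix(rep(vals, each = N), N, 3,
                   dimnames = list(NULL, c("u", "v", "w")))
  if (spec$eta > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(spec$seed)
    if (spec$per_species_independent) {
      xi <- matrix(rnorm(3 * N), N, 3)
    } else {
      xi <- matrix(rnorm(N), N, 3)
    }
    fields <- fields * (1 + spec$eta * xi)
    fields[fields < 0] <- 0
  }
  fields
}
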