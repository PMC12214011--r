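# shared fixtures: reference parameter sets and small domains

ref_params <- function(...) reference_nondim(...)

# random valid nondimensional parameter draws (kinetics only), used by
# property-style tests; treatment inputs kept small enough for feasibility
random_params <- function(n, seed = 1) {
  set.seed(seed)
  replicate(n, simplify = FALSE, {
    nondim_params(
      delta_u = runif(1, 1, 500), delta_w = runif(1, 1, 500),
      alpha = runif(1, 0.01, 0.15),
      mu_u = runif(1, 0.1, 0.3), mu_w = runif(1, 30, 80),
      rho_u = runif(1, 0.3, 1), rho_w = runif(1, 1, 4),
      sigma_u = runif(1, 0, 0.03), sigma_w = runif(1, 0, 2),
      gamma_v = runif(1, 0.05, 0.2), gamma_w = runif(1, 5e-4, 5e-3))
  })
}

random_state <- function() {
  c(u = runif(1, 0.01, 1), v = runif(1, 0.01, 0.95), w = runif(1, 0, 0.5))
}

fd_jacobian <- function(state, params, h = 1e-6) {
  J <- matrix(0, 3, 3)
  for (j in 1:3) {
    sp <- state; sm <- state
    sp[j] <- sp[j] + h; sm[j] <- sm[j] - h
    J[, j] <- (reaction_rates(sp, params) - reaction_rates(sm, params)) /
      (2 * h)
  }
  J
}
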