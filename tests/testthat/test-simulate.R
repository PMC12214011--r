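test_that("Laplacian stencils are exact where they should be", {
  dom1 <- domain_interval(L = 10, m = 201)
  L1 <- build_laplacian(dom1)
  expect_equal(max(abs(L1 %*% rep(3.7, dom1$N))), 0)

  # eigenfunction cos(pi x / L): second-order convergence
  errs <- sapply(c(101, 201, 401), function(m) {
    d <- domain_interval(L = 10, m = m)
    f <- cos(pi * d$x / d$L)
    max(abs(as.numeric(build_laplacian(d) %*% f) + (pi / d$L)^2 * f))
  })
  orders <- log2(errs[-3] / errs[-1])
  expect_true(all(orders > 1.8 & orders < 2.2))

  # 2D 9-point stencil: constants annihilated, quadratics exact inside
  dom2 <- domain_square(L = 6, m = 31)
  L2 <- build_laplacian(dom2)
  expect_equal(max(abs(L2 %*% rep(1.5, dom2$N))), 0)
  q <- dom2$x^2 + dom2$y^2
  interior <- !dom2$boundary &
    rowSums(matrix(dom2$boundary[dom2$nb], dom2$N)) == 0
  expect_equal(as.numeric((L2 %*% q))[interior],
               rep(4, sum(interior)), tolerance = 1e-10)

  # disc: constant annihilation across the stair-step rim
  dd <- domain_disc(L = 6, m = 25)
  expect_equal(max(abs(build_laplacian(dd) %*% rep(2, dd$N))), 0)
})

test_that("homogeneous PDE initial data tracks the ODE solution", {
  p <- ref_params(sigma_u = 0.014, sigma_w = 0.5)
  eq <- Filter(function(e) e$stable, coexistence_equilibria(p))[[1]]
  proto <- make_protocol("constant", sigma_u = 0.014, sigma_w = 0.5,
                         T_final = 100)
  times <- seq(0, 100, by = 5)
  ode <- simulate_model(eq$state * 1.05, p, proto, dom = NULL,
                        times = times)
  dom <- domain_interval(L = 30, m = 64)
  ic <- matrix(rep(eq$state * 1.05, each = dom$N), dom$N, 3)
  pde <- simulate_model(ic, p, proto, dom, times = times,
                        atol = 1e-11, rtol = 1e-11)
  for (k in seq_along(times)) {
    for (sp in 1:3) {
      expect_lt(max(abs(pde$fields[, sp, k] - ode$fields[1, sp, k])), 1e-6)
    }
  }
})

test_that("linear-regime pattern growth follows the dispersion relation", {
  p <- ref_params(sigma_u = 0.018, sigma_w = 0.5)
  eq <- Filter(function(e) e$stable, coexistence_equilibria(p))[[1]]
  tt <- turing_test(p, eq)
  expect_true(tt$unstable)
  J <- reaction_jacobian(eq$state, p)
  # put the critical mode exactly on the grid: k = n pi / L
  n_mode <- 2
  L <- n_mode * pi / sqrt(tt$k_c2)
  dom <- domain_interval(L = L, m = 128)
  rate <- growth_rates(J, p$delta_u, p$delta_w, tt$k_c2)$max_re
  amp0 <- 1e-4
  ic <- matrix(rep(eq$state, each = dom$N), dom$N, 3)
  ic[, 2] <- ic[, 2] + amp0 * cos(n_mode * pi * dom$x / L)
  proto <- make_protocol("constant", sigma_u = 0.018, sigma_w = 0.5,
                         T_final = 40)
  traj <- simulate_model(ic, p, proto, dom, times = seq(0, 40, by = 5))
  a_t <- sapply(seq_along(traj$times), function(k) {
    v <- traj$fields[, 2, k] - mean(traj$fields[, 2, k])
    2 * mean(v * cos(n_mode * pi * dom$x / L))
  })
  measured <- (log(a_t[length(a_t)]) - log(a_t[1])) / 40
  expect_equal(measured, rate, tolerance = 0.1)
})

test_that("extinction time interpolates the threshold crossing", {
  # synthetic trajectory with exponential decay
  tms <- seq(0, 100, by = 1)
  v <- exp(-0.3 * tms)
  fields <- array(0, c(1, 3, length(tms)))
  for (sp in 1:3) fields[1, sp, ] <- v
  traj <- structure(list(times = tms, fields = fields, dom = NULL),
                    class = "trajectory")
  expect_equal(extinction_time(traj, 1e-6), -log(1e-6) / 0.3,
               tolerance = 1e-2)
  traj$fields[1, 2, ] <- 1 # never crosses
  expect_true(is.na(extinction_time(traj)))
})

test_that("spatial averages and kymograph exports behave", {
  dom <- domain_interval(L = 10, m = 21)
  tms <- seq(0, 1, by = 0.5)
  fields <- array(2, c(dom$N, 3, length(tms)))
  traj <- structure(list(times = tms, fields = fields, dom = dom),
                    class = "trajectory")
  sm <- summarise_trajectory(traj)
  expect_true(all(sm$means$v == 2))
  expect_equal(dim(sm$kymograph), c(length(tms), dom$N))

  # disc averages only use interior (masked) nodes
  dd <- domain_disc(L = 10, m = 15)
  fd <- array(runif(dd$N * 3 * 2), c(dd$N, 3, 2))
  trajd <- structure(list(times = c(0, 1), fields = fd, dom = dd),
                     class = "trajectory")
  expect_equal(summarise_trajectory(trajd)$means$u[1], mean(fd[, 1, 1]))
})

test_that("negative treatment inputs are rejected in simulation", {
  p <- ref_params()
  proto <- make_protocol("linear_ramp", ramp = "sigma_w", from = 0.5,
                         to = -1, T_final = 10)
  expect_error(simulate_model(c(0.1, 0.5, 0.01), p, proto, dom = NULL,
                              times = seq(0, 10)),
               "non-negative")
})

test_that("atto-fox floor does not perturb a patterned 1D run", {
  p <- ref_params(sigma_u = 0.014)
  eq <- Filter(function(e) e$stable,
               coexistence_equilibria(ref_params(sigma_u = 0.014,
                                                 sigma_w = 0)))[[1]]
  dom <- domain_interval(L = 30, m = 96)
  ic <- perturbed_ic(eq, perturbation_spec(eta = 0.1, seed = 5), dom)
  tri <- make_protocol("triangular_ramp", peak = 18, T_ramp = 300,
                       T_final = 300, sigma_u = 0.014)
  tri_floor <- make_protocol("triangular_ramp", peak = 18, T_ramp = 300,
                             T_final = 300, sigma_u = 0.014,
                             atto_fox_floor = 1e-15)
  tms <- seq(0, 300, by = 50)
  t1 <- simulate_model(ic, p, tri, dom, times = tms)
  t2 <- simulate_model(ic, p, tri_floor, dom, times = tms)
  expect_lt(max(abs(t1$fields - t2$fields)), 1e-10)
})

test_that("nonlinear tumour diffusion is conservative and Neumann", {
  # pure diffusion of v: total mass conserved, uniform state invariant
  p <- ref_params(sigma_u = 0.014, sigma_w = 0.5)
  dom <- domain_interval(L = 10, m = 64)
  eq <- Filter(function(e) e$stable, coexistence_equilibria(p))[[1]]
  ic <- matrix(rep(eq$state, each = dom$N), dom$N, 3)
  proto <- make_protocol("constant", sigma_u = 0.014, sigma_w = 0.5,
                         T_final = 5)
  traj <- simulate_model(ic, p, proto, dom, times = c(0, 5),
                         nonlinear_v = TRUE)
  # uniform equilibrium stays exactly uniform under the nonlinear flux
  expect_lt(diff(range(traj$fields[, 2, 2])), 1e-8)
})
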