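test_that("dispersion cubic reduces to the ODE characteristic polynomial", {
  for (p in random_params(20, seed = 81)) {
    st <- random_state()
    J <- reaction_jacobian(st, p)
    dc <- dispersion_coefficients(J, p$delta_u, p$delta_w, 0)
    cp <- -sum(diag(J))                      # lambda^2 coefficient
    c1 <- J[1, 1] * J[2, 2] + J[1, 1] * J[3, 3] + J[2, 2] * J[3, 3] -
      J[1, 2] * J[2, 1] - J[1, 3] * J[3, 1] - J[2, 3] * J[3, 2]
    c0 <- -det(J)
    expect_equal(dc$a2, cp, tolerance = 1e-12)
    expect_equal(dc$a1, c1, tolerance = 1e-12)
    expect_equal(dc$a0, c0, tolerance = 1e-12)
    expect_equal(dc$D, c0, tolerance = 1e-12)
  }
})

test_that("a0 equals the determinant of the mode matrix at any k2", {
  set.seed(91)
  for (p in random_params(15, seed = 91)) {
    st <- random_state()
    J <- reaction_jacobian(st, p)
    for (k2 in c(0.01, 0.5, 3)) {
      Mk <- J - diag(c(p$delta_u, 1, p$delta_w)) * k2
      dc <- dispersion_coefficients(J, p$delta_u, p$delta_w, k2)
      expect_equal(dc$a0, -det(Mk), tolerance = 1e-9 * max(1, abs(dc$a0)))
    }
  }
})

test_that("equal unit diffusivities give the expected specialisation", {
  p <- ref_params(sigma_u = 0.014, sigma_w = 0.5)
  st <- random_state()
  J <- reaction_jacobian(st, p)
  dc <- dispersion_coefficients(J, 1, 1, 0.3)
  expect_equal(dc$A, 1)
  expect_equal(dc$B, -(J[1, 1] + J[2, 2] + J[3, 3]), tolerance = 1e-12)
})

test_that("growth rates are roots of the cubic and match mode eigenvalues", {
  p <- ref_params(sigma_u = 0.018, sigma_w = 0.5)
  eq <- Filter(function(e) e$stable, coexistence_equilibria(p))[[1]]
  J <- reaction_jacobian(eq$state, p)
  # k = 0 at a stable state: all decaying
  expect_lt(growth_rates(J, 100, 100, 0)$max_re, 0)
  # strong diffusive damping at large k2
  expect_lt(growth_rates(J, 100, 100, 1e6)$max_re, -1e5)
  for (k2 in c(0.002, 0.02, 0.2)) {
    g <- growth_rates(J, 100, 100, k2)
    Mk <- J - diag(c(100, 1, 100)) * k2
    ev <- eigen(Mk)$values
    expect_equal(sort(Re(g$lambdas)), sort(Re(ev)), tolerance = 1e-8)
    # roots satisfy the cubic
    dc <- dispersion_coefficients(J, 100, 100, k2)
    for (lam in g$lambdas)
      expect_lt(Mod(lam^3 + dc$a2 * lam^2 + dc$a1 * lam + dc$a0), 1e-6)
  }
})

test_that("critical wavenumber is the argmin of a0 over positive k2", {
  expect_equal(critical_wavenumber(1, 0, -3), 1)
  expect_error(critical_wavenumber(1, 2, 3), "discriminant")
  set.seed(101)
  for (rep in 1:25) {
    A <- runif(1, 0.5, 50); B <- runif(1, -20, 20); C <- runif(1, -20, 20)
    if (4 * B^2 - 12 * A * C < 0) next
    kc2 <- critical_wavenumber(A, B, C)
    if (kc2 <= 0) next
    grid <- seq(1e-4, 4 * kc2, length.out = 20001)
    a0 <- A * grid^3 + B * grid^2 + C * grid
    expect_equal(grid[which.min(a0)], kc2, tolerance = 1e-3)
  }
})

test_that("Turing classification matches the patterned regimes", {
  # cancer-free states are never Turing-unstable
  p <- ref_params(sigma_u = 0.02, sigma_w = 0.5)
  cf <- cancer_free_equilibrium(p)
  expect_false(turing_test(p, cf)$unstable)

  # inside the instability band at high effector contrast
  p_in <- ref_params(sigma_u = 0.018, sigma_w = 0.5)
  eq <- Filter(function(e) e$stable, coexistence_equilibria(p_in))[[1]]
  tt <- turing_test(p_in, eq)
  expect_true(tt$unstable)
  J <- reaction_jacobian(eq$state, p_in)
  expect_gt(growth_rates(J, 100, 100, tt$k_c2)$max_re, 0)

  # equal diffusivities cannot destabilise an ODE-stable state
  p_eq <- ref_params(sigma_u = 0.018, sigma_w = 0.5, delta_u = 1,
                     delta_w = 1)
  eq2 <- Filter(function(e) e$stable, coexistence_equilibria(p_eq))[[1]]
  expect_false(turing_test(p_eq, eq2)$unstable)
  J2 <- reaction_jacobian(eq2$state, p_eq)
  k2g <- seq(1e-3, 10, length.out = 300)
  a0g <- vapply(k2g, function(x)
    dispersion_coefficients(J2, 1, 1, x)$a0, numeric(1))
  expect_true(all(a0g > 0))
})

test_that("unstable modes are real (no wave instabilities) in scanned regimes", {
  set.seed(111)
  for (su in seq(0.0165, 0.0195, length.out = 7)) {
    p <- ref_params(sigma_u = su, sigma_w = 0.5)
    st <- Filter(function(e) e$stable, coexistence_equilibria(p))
    if (!length(st)) next
    J <- reaction_jacobian(st[[1]]$state, p)
    for (k2 in seq(0.004, 0.1, length.out = 25)) {
      g <- growth_rates(J, 100, 100, k2)
      if (g$max_re > 0)
        expect_lt(abs(Im(g$lambdas[1])), 1e-10)
    }
  }
})

test_that("cancer-free (u,w) subsystem is triangular and never destabilised", {
  for (p in random_params(30, seed = 121)) {
    den <- p$mu_u * (p$mu_w + p$sigma_w) - p$rho_u * p$sigma_w
    if (den <= 0) next
    cf <- cancer_free_equilibrium(p)
    J <- reaction_jacobian(cf$state, p)
    expect_equal(J[3, 1], 0)   # (u,w) block is triangular at v = 0
    if (!cf$stable) next
    for (k2 in c(0.01, 0.1, 1, 10)) {
      sub <- matrix(c(J[1, 1] - p$delta_u * k2, J[1, 3],
                      0, J[3, 3] - p$delta_w * k2), 2, 2, byrow = TRUE)
      expect_true(all(Re(eigen(sub)$values) < 0))
    }
  }
})

test_that("Turing-space scan has bands at the coexistence boundary", {
  p <- ref_params()
  su <- seq(0.012, 0.022, length.out = 26)
  sw <- seq(0, 3, length.out = 16)
  lab <- scan_turing_plane(p, su, sw)
  expect_true(all(lab %in% c("no_coexistence", "coex_stable_all",
                             "coex_turing_unstable")))
  expect_true(any(lab == "coex_turing_unstable"))
  # Turing cells sit adjacent to the loss of stable coexistence: in each
  # sigma_w row with instability, the unstable band touches the boundary of
  # the stable-coexistence region
  for (j in seq_along(sw)) {
    row <- lab[, j]
    tu <- which(row == "coex_turing_unstable")
    if (!length(tu)) next
    after <- row[(max(tu) + 1):length(row)]
    expect_true(length(after) == 0 || after[1] != "coex_stable_all")
  }
  # IL-2 diffusivity has no visible effect on the Turing-cell count
  p2 <- ref_params(delta_w = 1000)
  lab2 <- scan_turing_plane(p2, su, sw)
  expect_equal(sum(lab2 == "coex_turing_unstable"),
               sum(lab == "coex_turing_unstable"), tolerance = 0.1)
})
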