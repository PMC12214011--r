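# Continuation runs at a moderate interval mesh; the acceptance checks use
# the reference resolution (m = 256) for the printed fold location.

test_that("steady residual vanishes for constants and matches the stencil", {
  p <- ref_params(sigma_u = 0.014, sigma_w = 0.5)
  dom <- domain_interval(L = 30, m = 64)
  eq <- Filter(function(e) e$stable, coexistence_equilibria(p))[[1]]
  f0 <- matrix(rep(eq$state, each = dom$N), dom$N, 3)
  expect_lt(max(abs(steady_residual(f0, p, dom))), 1e-12)

  # dual assembly: sparse-operator evaluation vs the simulation stencil
  set.seed(5)
  f <- f0 * (1 + 0.2 * matrix(runif(3 * dom$N, -1, 1), dom$N, 3))
  R1 <- steady_residual(f, p, dom)
  kin <- with(p, c(alpha, mu_u, rho_u, mu_w, rho_w, gamma_v, gamma_w))
  R2 <- matrix(turimm:::rhs_core(0, c(f), dom$nb, dom$nbf, dom$h, dom$dim,
                                 p$delta_u, p$delta_w, kin, p$sigma_u,
                                 p$sigma_w, FALSE, integer(0), 0, FALSE, 0),
               dom$N, 3)
  expect_equal(R1, R2, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("small cosine perturbations follow the linearised operator", {
  p <- ref_params(sigma_u = 0.014, sigma_w = 0.5)
  dom <- domain_interval(L = 30, m = 256)
  eq <- Filter(function(e) e$stable, coexistence_equilibria(p))[[1]]
  f0 <- matrix(rep(eq$state, each = dom$N), dom$N, 3)
  k <- pi / dom$L
  eps <- 1e-7
  f <- f0
  f[, 2] <- f[, 2] + eps * cos(k * dom$x)
  R <- steady_residual(f, p, dom)
  J <- reaction_jacobian(eq$state, p)
  # continuum prediction: column 2 of M_k times the perturbation
  Mk_col <- (J - diag(c(p$delta_u, 1, p$delta_w)) * k^2)[, 2]
  for (sp in 1:3)
    expect_equal(R[, sp], eps * Mk_col[sp] * cos(k * dom$x),
                 tolerance = 1e-3)
})

test_that("homogeneous branch agrees with the scalar equilibrium analysis", {
  p <- ref_params(sigma_w = 0.5)
  hb <- homogeneous_branch(p, "sigma_u", v0 = seq(0.05, 0.95, by = 0.05))
  for (i in seq_len(nrow(hb))) {
    pp <- p; pp$sigma_u <- hb$parameter[i]
    if (pp$sigma_u < 0) next
    roots <- coexistence_roots(pp, method = "quintic")
    expect_lt(min(abs(roots - hb$v0[i])), 1e-8)
  }
})

test_that("discretised leading eigenvalues match the mode decomposition", {
  p <- ref_params(sigma_u = 0.014, sigma_w = 0.5)
  dom <- domain_interval(L = 30, m = 96)
  eq <- Filter(function(e) e$stable, coexistence_equilibria(p))[[1]]
  f0 <- matrix(rep(eq$state, each = dom$N), dom$N, 3)
  lead <- turimm:::.leading_eigs(f0, p, dom, build_laplacian(dom),
                                 n_lead = 8)
  J <- reaction_jacobian(eq$state, p)
  # discrete symbol of the 3-point stencil: -(4/h^2) sin^2(k h / 2)
  modes <- lapply(0:12, function(n) {
    k <- n * pi / dom$L
    k2d <- 4 / dom$h^2 * sin(k * dom$h / 2)^2
    eigen(J - diag(c(p$delta_u, 1, p$delta_w)) * k2d,
          only.values = TRUE)$values
  })
  pred <- sort(Re(unlist(modes)), decreasing = TRUE)[1:8]
  expect_equal(sort(Re(lead), decreasing = TRUE), pred, tolerance = 1e-6)
})

test_that("pseudo-arclength continuation reproduces the homogeneous fold", {
  # the upper/lower coexistence pair merges in a fold visible to the scalar
  # analysis; trace it with the PDE machinery on a degenerate 3-node domain
  p <- ref_params(sigma_u = 0.018, sigma_w = 0.5)
  dom <- domain_interval(L = 1, m = 3)
  eqs <- coexistence_equilibria(p)
  eq <- eqs[[which.max(vapply(eqs, function(e) e$state["v"], numeric(1)))]]
  f0 <- matrix(rep(eq$state, each = dom$N), dom$N, 3)
  br <- continue_branch(f0, p, dom, "sigma_u", direction = +1,
                        n_steps = 150, ds0 = 5e-3, ds_max = 2e-2,
                        p_range = c(0.005, 0.04))
  expect_gt(length(br$folds), 0)
  # the scalar route: fold where the quintic's upper pair merges
  su_grid <- seq(0.022, 0.026, by = 1e-4)
  n_roots <- sapply(su_grid, function(su) {
    pp <- p; pp$sigma_u <- su
    length(coexistence_roots(pp, method = "quintic"))
  })
  su_fold_scalar <- su_grid[max(which(n_roots == 2))]
  expect_equal(br$folds[1], su_fold_scalar, tolerance = 5e-3)
  # points on the branch coincide with quintic roots
  mid <- br$points$parameter[10]
  pp <- p; pp$sigma_u <- mid
  expect_lt(min(abs(coexistence_roots(pp, method = "quintic") -
                      br$points$mean[10])), 1e-6)
})

test_that("branch switching yields the reflected branch for flipped modes", {
  # an odd critical mode, so that the phase flip is the x -> L - x
  # reflection (for even modes the two sub-branches are distinct states)
  p <- ref_params(sigma_w = 0.5)
  dom <- domain_interval(L = 22, m = 128)
  on <- turing_onset(p, dom, "sigma_u", bracket = c(0.014, 0.0195))
  expect_equal(on$mode, 1)
  sp <- switch_branch(on, p, dom, "sigma_u", mode = on$mode, amp = 0.04)
  sm <- switch_branch(on, p, dom, "sigma_u", mode = -on$mode, amp = 0.04)
  expect_true(sp$converged && sm$converged)
  expect_equal(sp$parameter, sm$parameter, tolerance = 1e-8)
  # x -> L - x reflection maps one onto the other
  expect_equal(sp$fields, sm$fields[dom$N:1, ], tolerance = 1e-7,
               ignore_attr = TRUE)
})

test_that("the primary Turing branch is subcritical", {
  p <- ref_params(sigma_w = 0.5)
  dom <- domain_interval(L = 30, m = 128)
  on <- turing_onset(p, dom, "sigma_u", bracket = c(0.014, 0.0195))
  s1 <- switch_branch(on, p, dom, "sigma_u", amp = 0.03)
  s2 <- switch_branch(on, p, dom, "sigma_u", amp = 0.06)
  pp <- p; pp$sigma_u <- s1$parameter
  br <- continue_branch(s1$fields, pp, dom, "sigma_u", n_steps = 25,
                        ds0 = 0.02, ds_max = 0.05,
                        p_range = c(0.005, 0.03), seed2 = s2)
  # homogeneous state is stable below the onset (Turing destabilises
  # as sigma_u increases through it)
  expect_identical(classify_criticality(br, on$parameter, stable_side = -1),
                   "subcritical")
  # orientation covariance: flipping the stable side flips the verdict
  expect_identical(classify_criticality(br, on$parameter, stable_side = +1),
                   "supercritical")
})

test_that("criticality classification on known branch geometries", {
  # synthetic supercritical geometry: branch grows into the unstable side
  fake <- structure(list(points = data.frame(
    parameter = 0.02 + seq(0, 1e-3, length.out = 12))), class = "branch")
  expect_identical(classify_criticality(fake, 0.02, stable_side = -1),
                   "supercritical")
  expect_identical(classify_criticality(fake, 0.02, stable_side = +1),
                   "subcritical")
})
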