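test_that("Gaussian kernel matches its closed form and exact L1 norm", {
  w <- gaussian_kernel(K = 1, beta = 1)
  expect_equal(w$evaluate(0.7, 0.7), 1)
  expect_equal(w$evaluate(-3.2, -3.2), 1)
  expect_equal(w$evaluate(0, 2), exp(-2))
  expect_equal(gaussian_kernel(K = 3, beta = 2)$analytic_l1,
               3 * 2 * sqrt(2 * pi))
  # grid L1 norm converges to the analytic value on a wide enough box
  g <- grid_spec(1, L = 8, M = 1024)
  gl1 <- grid_integral(g, abs(kernel_profile(w, g)))
  expect_lt(abs(gl1 - w$analytic_l1) / w$analytic_l1, 1e-6)
  expect_error(gaussian_kernel(K = -1), "positive")
  expect_error(gaussian_kernel(beta = 0), "positive")
})

test_that("Mexican hat kernel: center value, cancellation, sign change", {
  w <- mexican_hat_kernel(K1 = 2, K2 = 1, beta1 = 1, beta2 = 2)
  expect_equal(w$evaluate(1.3, 1.3), 2 - 1)
  # locally excitatory, remotely inhibitory: sign change on the profile
  expect_gt(w$evaluate(0, 0), 0)
  expect_lt(w$evaluate(0, 3), 0)
  u0 <- sqrt(8 * log(2) / 3)  # zero crossing of the closed form
  expect_lt(abs(w$evaluate(0, u0)), 1e-12)
  # identical Gaussians cancel exactly
  w0 <- mexican_hat_kernel(K1 = 1, K2 = 1, beta1 = 1.5, beta2 = 1.5)
  expect_equal(w0$evaluate(0, seq(-5, 5, by = 0.1)), rep(0, 101))
  expect_equal(w0$analytic_l1, 0)
  # analytic |w| L1 norm against an independent quadrature oracle
  oracle <- stats::integrate(function(u) abs(2 * exp(-u^2 / 2) -
                                               exp(-u^2 / 8)),
                             -Inf, Inf, rel.tol = 1e-12)$value
  expect_equal(w$analytic_l1, oracle, tolerance = 1e-9)
  # no sign change when the narrow Gaussian dominates everywhere
  wn <- mexican_hat_kernel(K1 = 1, K2 = 2, beta1 = 2, beta2 = 1)
  o2 <- stats::integrate(function(u) abs(exp(-u^2 / 8) -
                                           2 * exp(-u^2 / 2)),
                         -Inf, Inf, rel.tol = 1e-12)$value
  expect_equal(wn$analytic_l1, o2, tolerance = 1e-7)
})

test_that("homogeneous kernels are shift invariant on random triples", {
  set.seed(101)
  for (k in list(gaussian_kernel(), mexican_hat_kernel(2, 1, 1, 2),
                 exponential_kernel(0.7))) {
    x <- runif(100, -5, 5); y <- runif(100, -5, 5)
    z <- runif(100, -3, 3)
    expect_equal(k$evaluate(x + z, y + z), k$evaluate(x, y),
                 tolerance = 1e-14)
  }
})

test_that("exponential kernel has unit inner L1 norm", {
  k <- exponential_kernel(beta = 2)
  expect_equal(k$analytic_l1, 1)
  expect_equal(k$evaluate(1, 1), 1 / 4)  # 1/(2 beta)
  oracle <- stats::integrate(function(u) exp(-abs(u) / 2) / 4,
                             -Inf, Inf)$value
  expect_equal(oracle, 1, tolerance = 1e-8)
})

test_that("anisotropy factor: unit at origin, isotropy at chi = 0", {
  for (chi in c(0, 0.3, 0.9)) {
    expect_equal(anisotropy_factor(chi, c(0, 0)), 1)
  }
  # chi = 0: depends on |x| only
  a1 <- anisotropy_factor(0, c(1, 0), beta_lr = 1.5)
  a2 <- anisotropy_factor(0, c(0, 1), beta_lr = 1.5)
  a3 <- anisotropy_factor(0, c(1, 1) / sqrt(2), beta_lr = 1.5)
  expect_equal(a1, a2)
  expect_equal(a1, a3)
  # anisotropic closed-form value
  expect_equal(anisotropy_factor(0.5, c(1, 0), beta_lr = 1),
               exp(-0.125))
  expect_error(anisotropy_factor(1, c(1, 0)), "chi")
  expect_error(anisotropy_factor(-0.1, c(1, 0)), "chi")
})

test_that("synthetic orientation maps are valid and reproducible", {
  g <- grid_spec(2, 5, 32)
  om1 <- orientation_map_synthetic(g, n_modes = 8, seed = 7)
  om2 <- orientation_map_synthetic(g, n_modes = 8, seed = 7)
  expect_true(all(om1$theta >= 0 & om1$theta < pi))
  expect_identical(om1$theta, om2$theta)
  om3 <- orientation_map_synthetic(g, n_modes = 8, seed = 8)
  expect_false(identical(om1$theta, om3$theta))
  # single plane wave: theta is linear in x modulo pi
  oml <- orientation_map_synthetic(g, n_modes = 1)
  nodes <- grid_nodes(g)
  kmag <- 2 * pi / (2 * g$L)
  expect_equal(oml$theta, (kmag * nodes[, 1] / 2) %% pi,
               tolerance = 1e-12)
  expect_error(orientation_map_synthetic(grid_spec(1, 5, 32)), "2D")
})

test_that("long-range kernel: diagonal value, non-homogeneity", {
  g <- grid_spec(2, 5, 16)
  om <- orientation_map_synthetic(g, n_modes = 8, seed = 3)
  bt <- pi / 8
  k <- long_range_kernel(eps_lr = 0.2, chi = 0.4, beta_lr = 2,
                         beta_theta = bt, theta_map = om)
  nodes <- grid_nodes(g)
  for (i in c(1, 50, 200)) {
    expect_equal(k$evaluate(nodes[i, , drop = FALSE],
                            nodes[i, , drop = FALSE]),
                 0.2 / (sqrt(2 * pi) * bt), tolerance = 1e-12)
  }
  # a shift that changes the value exists when theta is non-constant
  x <- nodes[10, , drop = FALSE]; y <- nodes[40, , drop = FALSE]
  shifts <- nodes[c(5, 17, 33, 120), , drop = FALSE]
  moved <- vapply(seq_len(nrow(shifts)), function(s) {
    k$evaluate(x + shifts[s, , drop = FALSE],
               y + shifts[s, , drop = FALSE])
  }, numeric(1))
  expect_gt(max(abs(moved - k$evaluate(x, y))), 1e-6)
  expect_false(k$homogeneous)
  # constant orientation, chi = 0: homogeneous Gaussian profile
  kh <- long_range_kernel(eps_lr = 0.2, chi = 0, beta_lr = 2,
                          beta_theta = bt, theta_map = 0.3)
  expect_true(kh$homogeneous)
  d <- sqrt(sum((nodes[5, ] - nodes[60, ])^2))
  expect_equal(kh$evaluate(nodes[5, , drop = FALSE],
                           nodes[60, , drop = FALSE]),
               0.2 * exp(-d^2 / 8) / (sqrt(2 * pi) * bt),
               tolerance = 1e-12)
  expect_error(long_range_kernel(theta_map = NULL), "orientation")
})

test_that("combined local + long-range kernel sums pointwise", {
  g <- grid_spec(2, 5, 16)
  om <- orientation_map_synthetic(g, n_modes = 8, seed = 3)
  loc <- gaussian_kernel(1, 1, N = 2)
  lr <- long_range_kernel(eps_lr = 0.1, chi = 0.3, beta_lr = 2,
                          beta_theta = pi / 8, theta_map = om)
  k <- pva_kernel(loc, lr)
  nodes <- grid_nodes(g)
  x <- nodes[7, , drop = FALSE]; y <- nodes[90, , drop = FALSE]
  expect_equal(k$evaluate(x, y),
               loc$evaluate(x, y) + lr$evaluate(x, y))
  expect_equal(k$evaluate(x, x), loc$evaluate(x, x) + lr$evaluate(x, x))
  expect_false(k$homogeneous)
  # zero long-range part is the additive identity
  k0 <- pva_kernel(loc, zero_kernel())
  expect_equal(k0$evaluate(x, y), loc$evaluate(x, y))
  expect_true(k0$homogeneous)
})

test_that("sigmoid gain: symmetry and slope bound", {
  G <- sigmoid_gain()
  expect_equal(G$apply(0), 0.5)
  a <- seq(-8, 8, by = 0.25)
  expect_equal(G$apply(a) + G$apply(-a), rep(1, length(a)))
  expect_equal(G$bound, 1)
  expect_equal(G$slope_bound, 0.25)
  # Lipschitz with the slope bound on many random pairs
  set.seed(55)
  u <- runif(1e4, -10, 10); v <- runif(1e4, -10, 10)
  expect_true(all(abs(G$apply(u) - G$apply(v)) <=
                    0.25 * abs(u - v) + 1e-14))
  # sharpest slope attained at zero
  eps <- 1e-6
  expect_equal((G$apply(eps) - G$apply(-eps)) / (2 * eps), 0.25,
               tolerance = 1e-6)
})

test_that("diffusion coefficients satisfy their growth contracts", {
  set.seed(56)
  a <- runif(1e4, -20, 20); b <- runif(1e4, -20, 20)
  lin <- linear_diffusion(0.7)
  expect_true(all(abs(lin$apply(a)) <= lin$linear_growth * (1 + abs(a))))
  expect_true(all(abs(lin$apply(a) - lin$apply(b)) <=
                    lin$lipschitz * abs(a - b) + 1e-12))
  th <- tanh_diffusion(2)
  expect_true(all(abs(th$apply(a) - th$apply(b)) <=
                    th$lipschitz * abs(a - b) + 1e-12))
  expect_true(all(abs(th$apply(a)) <= 2))
})

test_that("FFT and dense drift paths agree on homogeneous kernels", {
  g <- grid_spec(1, 8, 64)
  k <- gaussian_kernel(1, 1)
  Y <- initial_condition(g, list(type = "bump", height = 2, width = 1.5))
  f1 <- nonlocal_drift(Y, k, sigmoid_gain(), g, method = "fft")
  f2 <- nonlocal_drift(Y, k, sigmoid_gain(), g, method = "dense")
  expect_lt(max(abs(f1 - f2)), 1e-10)
  g2 <- grid_spec(2, 5, 12)
  k2 <- gaussian_kernel(1, 1, N = 2)
  Y2 <- initial_condition(g2, list(type = "bump"))
  d1 <- nonlocal_drift(Y2, k2, sigmoid_gain(), g2, method = "fft")
  d2 <- nonlocal_drift(Y2, k2, sigmoid_gain(), g2, method = "dense")
  expect_lt(max(abs(d1 - d2)), 1e-10)
})
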