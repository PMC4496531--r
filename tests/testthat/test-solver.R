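test_that("nonlocal drift reduces to the inner L1 norm for unit gain", {
  g <- grid_spec(1, 10, 128)
  k <- gaussian_kernel(1, 1)
  set.seed(301)
  Y <- stats::rnorm(g$M)
  # G == 1: drift is the (periodic, truncated) L1 norm, Y-independent
  f <- nonlocal_drift(Y, k, constant_gain(1), g)
  W1 <- grid_integral(g, kernel_profile(k, g))
  expect_equal(f, rep(W1, g$M), tolerance = 1e-12)
  # constant field, homogeneous kernel: constant drift G(c) * int w
  c0 <- 0.8
  fc <- nonlocal_drift(rep(c0, g$M), k, sigmoid_gain(), g)
  expect_equal(fc, rep(sigmoid_gain()$apply(c0) * W1, g$M),
               tolerance = 1e-12)
  # zero kernel: zero drift
  expect_equal(nonlocal_drift(Y, zero_kernel(), sigmoid_gain(), g),
               rep(0, g$M))
})

test_that("noise operator is linear and matches its closed forms", {
  g <- grid_spec(1, 10, 128)
  phi <- smoothing_gaussian(0.5)
  set.seed(302)
  Y <- stats::rnorm(g$M); u <- stats::rnorm(g$M)
  # sigma == 1: plain convolution with phi
  b1 <- noise_operator_apply(Y, u, phi, constant_diffusion(1), g)
  expect_equal(b1, grid_conv(g, smoothing_values(phi, g), u),
               tolerance = 1e-13)
  # u = 0 gives 0
  expect_equal(noise_operator_apply(Y, rep(0, g$M), phi,
                                    linear_diffusion(2), g), rep(0, g$M))
  # multiplicative case: pointwise lambda * Y * (phi * u)
  b2 <- noise_operator_apply(Y, u, phi, linear_diffusion(0.7), g)
  expect_equal(b2, 0.7 * Y * grid_conv(g, smoothing_values(phi, g), u),
               tolerance = 1e-13)
  # linearity in u
  v <- stats::rnorm(g$M)
  expect_equal(noise_operator_apply(Y, 2 * u - 3 * v, phi,
                                    linear_diffusion(0.7), g),
               2 * b2 - 3 * noise_operator_apply(Y, v, phi,
                                                 linear_diffusion(0.7), g),
               tolerance = 1e-12)
})

test_that("pure decay is integrated exactly for any step size", {
  g <- grid_spec(1, 10, 64)
  cf <- nf_config(grid = g, kernel = zero_kernel(),
                  gain = constant_gain(0),
                  diffusion = constant_diffusion(0),
                  phi = smoothing_gaussian(0.5), T = 2, dt = 0.25,
                  seed = 5, y0 = list(type = "bump", height = 2))
  p <- simulate_field(cf)
  exact <- outer(exp(-p$times), p$values[1, ])
  expect_lt(max(abs(p$values - exact)), 1e-12)
})

test_that("constant drift reproduces the scalar linear ODE exactly", {
  g <- grid_spec(1, 10, 64)
  k <- gaussian_kernel(1, 1)
  W1 <- grid_integral(g, kernel_profile(k, g))
  cf <- nf_config(grid = g, kernel = k, gain = constant_gain(0.7),
                  diffusion = constant_diffusion(0),
                  phi = smoothing_gaussian(0.5), T = 2, dt = 0.05,
                  seed = 6, y0 = list(type = "constant", value = 0.3))
  p <- simulate_field(cf)
  closed <- exp(-p$times) * 0.3 + (1 - exp(-p$times)) * 0.7 * W1
  expect_lt(max(abs(p$values - matrix(closed, length(closed), g$M))),
            1e-12)
})

test_that("decoupled nodes follow the OU stationary variance", {
  g <- grid_spec(1, 10, 64)
  phi <- smoothing_gaussian(0.5)
  cf <- nf_config(grid = g, kernel = zero_kernel(),
                  gain = constant_gain(0),
                  diffusion = constant_diffusion(1), phi = phi,
                  T = 6, dt = 0.005, seed = 7,
                  y0 = list(type = "constant", value = 0))
  ns <- round(cf$T / cf$dt)
  keep <- c(round(0.7 * ns), round(0.85 * ns), ns) + 1
  ens <- simulate_ensemble(cf, replicates = 2000, keep = keep)
  # per-replicate statistic, replicate-level standard error
  vr <- apply(ens$values^2, 3, mean)
  target <- smoothing_l2(phi, g)^2 / 2
  se <- stats::sd(vr) / sqrt(length(vr))
  expect_lt(abs(mean(vr) - target), 3 * se + 0.01 * target)
})

test_that("simulation is reproducible and respects T = 0", {
  g <- grid_spec(1, 10, 64)
  cf <- nf_config(grid = g, kernel = gaussian_kernel(1, 1),
                  gain = sigmoid_gain(),
                  diffusion = linear_diffusion(0.5),
                  phi = smoothing_gaussian(0.5), T = 0.5, dt = 0.05,
                  seed = 11, y0 = list(type = "bump"))
  p1 <- simulate_field(cf)
  p2 <- simulate_field(cf)
  expect_identical(p1$values, p2$values)
  cf0 <- cf; cf0$T <- 0
  p0 <- simulate_field(cf0)
  expect_equal(nrow(p0$values), 1)
  expect_equal(p0$times, 0)
})

test_that("simulation refuses kernels failing C2' unless forced", {
  g <- grid_spec(1, 10, 64)
  cf <- nf_config(grid = g, kernel = counterexample_kernel(),
                  gain = sigmoid_gain(),
                  diffusion = constant_diffusion(1),
                  phi = smoothing_gaussian(0.5), T = 0.1, dt = 0.05,
                  seed = 12, y0 = list(type = "constant", value = 0))
  expect_error(simulate_field(cf), "C2'")
  p <- simulate_field(cf, force = TRUE)
  expect_equal(nrow(p$values), 3)
})

test_that("Picard iteration on frozen noise contracts super-geometrically", {
  g <- grid_spec(1, 10, 64)
  k <- gaussian_kernel(1, 1)
  phi <- smoothing_gaussian(0.5)
  Y0 <- initial_condition(g, list(type = "bump"))
  set.seed(303)
  noise <- frozen_noise(g, 20, 0.05, seed = 303)
  res <- picard_solve(Y0, T = 1, dt = 0.05, kernel = k,
                      gain = sigmoid_gain(),
                      diffusion = linear_diffusion(0.5), phi = phi,
                      grid = g, noise = noise)
  H <- res$trace$H
  expect_true(res$trace$converged)
  # eventually decreasing, with decreasing contraction ratios (the
  # factorial-type tail of the fixed-point bound)
  expect_true(all(diff(H) < 0))
  ratios <- H[-1] / H[-length(H)]
  expect_true(all(diff(ratios[-1]) < 0.05))
  expect_lt(utils::tail(ratios, 1), 0.1)
})

test_that("noiseless gainless Picard converges immediately to decay", {
  g <- grid_spec(1, 10, 64)
  Y0 <- initial_condition(g, list(type = "bump"))
  noise <- frozen_noise(g, 10, 0.1, seed = 304)
  res <- picard_solve(Y0, T = 1, dt = 0.1, kernel = zero_kernel(),
                      gain = constant_gain(0),
                      diffusion = constant_diffusion(0),
                      phi = smoothing_gaussian(0.5), grid = g,
                      noise = noise)
  expect_lte(res$trace$iterations, 2)
  exact <- outer(exp(-res$path$times), Y0)
  expect_lt(max(abs(res$path$values - exact)), 1e-12)
})

test_that("Euler and Picard agree increasingly under dt refinement", {
  g <- grid_spec(1, 10, 64)
  k <- gaussian_kernel(1, 1)
  phi <- smoothing_gaussian(0.5)
  Y0 <- initial_condition(g, list(type = "bump"))
  fine <- frozen_noise(g, 80, 1 / 80, seed = 305)
  sup_diffs <- vapply(0:3, function(lev) {
    fac <- 2^(3 - lev)
    noise <- coarsen_noise(fine, fac)
    dt <- attr(noise, "dt")
    ns <- ncol(noise)
    pic <- picard_solve(Y0, T = 1, dt = dt, kernel = k,
                        gain = sigmoid_gain(),
                        diffusion = linear_diffusion(0.5), phi = phi,
                        grid = g, noise = noise)
    eul <- euler_path(Y0, dt, ns, k, sigmoid_gain(),
                      linear_diffusion(0.5), phi, g, noise)
    max(abs(eul - pic$path$values))
  }, numeric(1))
  expect_true(all(diff(sup_diffs) < 0))
})

test_that("weighted norm: closed cases and summation-order oracle", {
  g <- grid_spec(1, 10, 64)
  rho <- constant_weight(g, Lambda = 1)
  expect_equal(weighted_norm(rep(0, g$M), rho), 0)
  set.seed(306)
  Y <- stats::rnorm(g$M)
  expect_equal(weighted_norm(Y, rho), grid_l2_norm(g, Y))
  w <- runif(g$M, 0.5, 2)
  perm <- sample.int(g$M)
  expect_equal(weighted_norm(Y, w, g), weighted_norm(Y[perm], w[perm], g),
               tolerance = 1e-12)
  oracle <- sqrt(sum(sort(Y^2 * w * g$h)))  # stabilized summation order
  expect_equal(weighted_norm(Y, w, g), oracle, tolerance = 1e-12)
})

test_that("moment diagnostics: decay law, boundedness, preconditions", {
  g <- grid_spec(1, 10, 32)
  phi <- smoothing_gaussian(0.5)
  # noiseless decay: second moment falls as e^{-2t}
  cfd <- nf_config(grid = g, kernel = zero_kernel(),
                   gain = constant_gain(0),
                   diffusion = constant_diffusion(0), phi = phi,
                   T = 2, dt = 0.05, seed = 21,
                   y0 = list(type = "iid_gaussian", sd = 1))
  ensd <- simulate_ensemble(cfd, replicates = 120)
  m2 <- apply(ensd$values^2, 1, mean)
  expect_equal(m2, m2[1] * exp(-2 * ensd$times), tolerance = 1e-10)
  # bounded gain and diffusion: moments plateau
  cfb <- nf_config(grid = g, kernel = gaussian_kernel(1, 1),
                   gain = sigmoid_gain(), diffusion = tanh_diffusion(0.5),
                   phi = phi, T = 10, dt = 0.05, seed = 22,
                   y0 = list(type = "constant", value = 0))
  ensb <- simulate_ensemble(cfb, replicates = 150,
                            keep = seq(1, 201, by = 4))
  rep <- moment_diagnostics(ensb)
  expect_identical(rep$verdict, "bounded")
  # a single replicate is not an ensemble
  tiny <- simulate_ensemble(cfd, replicates = 1)
  expect_error(moment_diagnostics(tiny), "replicates")
})

test_that("random-field and Hilbert-space stepping coincide on shared noise", {
  g <- grid_spec(1, 10, 64)
  k <- gaussian_kernel(1, 1)
  rho <- rho_fourier(k, grid_spec(1, 10, 64))
  cf <- nf_config(grid = g, kernel = k, gain = sigmoid_gain(),
                  diffusion = linear_diffusion(0.5),
                  phi = smoothing_gaussian(0.5), T = 0.5, dt = 0.05,
                  seed = 31, y0 = list(type = "bump"))
  expect_lt(equivalence_check(cf, rho), 1e-10)
  # noiseless: exactly zero discrepancy
  cf0 <- cf; cf0$diffusion <- constant_diffusion(0)
  expect_equal(equivalence_check(cf0, rho), 0)
  # different seeds between the two runs: order-one discrepancy
  expect_gt(equivalence_check(cf, rho, seed_hs = 99), 1e-3)
})
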