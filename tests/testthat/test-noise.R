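test_that("white-noise increments carry the set-indexed covariance", {
  g <- grid_spec(1, 5, 64)
  dt <- 0.05
  set.seed(201)
  dW <- white_noise_increments(g, dt, n = 1e5)
  v <- dt * g$h
  # single-cell variance within 3 chi-square standard errors
  cellvar <- mean(dW[10, ]^2)
  se <- v * sqrt(2 / 1e5)
  expect_lt(abs(cellvar - v), 3 * se)
  # disjoint cells are uncorrelated
  cc <- mean(dW[10, ] * dW[40, ])
  expect_lt(abs(cc), 3 * v / sqrt(1e5))
  # additivity over a union of two cells
  u <- dW[10, ] + dW[11, ]
  expect_lt(abs(mean(u^2) - 2 * v), 3 * (2 * v) * sqrt(2 / 1e5))
})

test_that("smoothing by a delta recovers the raw increments", {
  g <- grid_spec(1, 5, 64)
  set.seed(202)
  dW <- white_noise_increments(g, 0.1)
  # zero kernel kills the field
  expect_equal(as.numeric(smoothed_increment(dW, smoothing_zero(), g)),
               rep(0, 64))
  # single-node mass 1/h acts as the convolution identity
  delta <- smoothing_custom(function(d) {
    (abs(if (is.matrix(d)) d[, 1] else d) < 1e-12) / g$h
  })
  sm <- smoothed_increment(dW, delta, g)
  expect_equal(as.numeric(sm), as.numeric(dW) / g$h, tolerance = 1e-12)
})

test_that("smoothed increments are linear and have the exact variance", {
  g <- grid_spec(1, 10, 64)
  phi <- smoothing_gaussian(0.5)
  set.seed(203)
  dW1 <- white_noise_increments(g, 0.2)
  dW2 <- white_noise_increments(g, 0.2)
  lhs <- smoothed_increment(3 * dW1 - 2 * dW2, phi, g)
  rhs <- 3 * smoothed_increment(dW1, phi, g) -
    2 * smoothed_increment(dW2, phi, g)
  expect_equal(as.numeric(lhs), as.numeric(rhs), tolerance = 1e-13)
  # ensemble variance at a node: dt * ||phi||^2
  dW <- white_noise_increments(g, 0.2, n = 4000)
  S <- smoothed_increment(dW, phi, g)
  target <- 0.2 * smoothing_l2(phi, g)^2
  vs <- mean(S^2)
  se <- stats::sd(as.numeric(S)^2) / sqrt(length(S))
  # nodes are correlated within a replicate; inflate the error allowance
  expect_lt(abs(vs - target), 10 * se)
})

test_that("theoretical covariance matches the Gaussian convolution law", {
  g <- grid_spec(1, 20, 256)
  beta <- 1
  phi <- smoothing_gaussian(beta)
  tc <- theoretical_covariance(phi, t = 2, g)
  closed <- 2 * beta * sqrt(pi) * exp(-tc$displacement^2 / (4 * beta^2))
  expect_lt(max(abs(tc$covariance - closed)), 1e-12)
  expect_equal(tc$covariance[tc$displacement == 0],
               2 * smoothing_l2(phi, g)^2)
  # t = 0: identically zero
  expect_equal(theoretical_covariance(phi, 0, g)$covariance, rep(0, 256))
  # symmetry in the displacement
  cv <- tc$covariance[order(abs(tc$displacement), tc$displacement)]
  expect_equal(tc$covariance, rev(tc$covariance)[c(256, 1:255)],
               tolerance = 1e-12)
})

test_that("empirical covariance of the smoothed field matches theory", {
  g <- grid_spec(1, 20, 128)
  phi <- smoothing_gaussian(1)
  set.seed(204)
  cmp <- covariance_comparison(phi, t = 1, g, replicates = 2000)
  expect_lt(cmp$max_error_in_se, 5)
  # compactly supported phi: covariance vanishes beyond the support sum
  ind <- smoothing_indicator(0.5)
  tci <- theoretical_covariance(ind, 1, g)
  far <- abs(tci$displacement) > 1 + g$h
  expect_equal(tci$covariance[far], rep(0, sum(far)))
})

test_that("shift modulus: exact values and Sobolev bound", {
  g <- grid_spec(1, 4, 512)
  ind <- smoothing_indicator(0.5)
  expect_equal(shift_modulus(ind, 0, g), 0)
  # indicator: modulus^2 = 2|z| exactly for commensurate shifts
  expect_equal(shift_modulus(ind, 0.25, g), sqrt(0.5), tolerance = 1e-12)
  expect_equal(shift_modulus(ind, 0.5, g), 1, tolerance = 1e-12)
  # Gaussian phi is W^{1,2}: modulus/|z| bounded by ||phi'||_{L2}
  gg <- grid_spec(1, 20, 1024)
  beta <- 1
  phig <- smoothing_gaussian(beta)
  dnorm2 <- sqrt(sqrt(pi) / (2 * beta))  # ||phi'||_{L2} closed form
  for (z in gg$h * c(1, 2, 4, 8)) {
    expect_lte(shift_modulus(phig, z, gg) / z, dnorm2 * (1 + 1e-6))
  }
  expect_error(shift_modulus(ind, 0.3 * g$h, g), "multiple")
})

test_that("Q-Wiener increments respect the eigen-structure", {
  g <- grid_spec(1, 10, 128)
  q <- q_spec(g, lambdas = c(2, 1, 0.5))
  set.seed(205)
  X <- q_wiener_increment(q, dt = 0.1, n = 8000)
  pr <- g$h * crossprod(q$basis, X)  # mode coefficients
  vars <- apply(pr, 1, stats::var)
  for (j in 1:3) {
    se <- (q$lambdas[j] * 0.1) * sqrt(2 / 8000)
    expect_lt(abs(vars[j] - q$lambdas[j] * 0.1), 4 * se)
  }
  # distinct modes are uncorrelated
  expect_lt(abs(stats::cor(pr[1, ], pr[2, ])), 4 / sqrt(8000))
  expect_lt(abs(stats::cor(pr[2, ], pr[3, ])), 4 / sqrt(8000))
  # all eigenvalues zero: the zero field
  q0 <- q_spec(g, lambdas = c(0, 0))
  expect_equal(as.numeric(q_wiener_increment(q0, 0.1)), rep(0, 128))
  expect_error(q_spec(g, lambdas = c(1, -0.1)), "nonnegative")
})

test_that("Q-Wiener covariance identity holds for random test functions", {
  g <- grid_spec(1, 10, 128)
  lam <- c(1.5, 1, 0.7, 0.4, 0.2)
  q <- q_spec(g, lambdas = lam)
  set.seed(206)
  gfun <- stats::rnorm(g$M); hfun <- stats::rnorm(g$M)
  dt <- 0.05
  X <- q_wiener_increment(q, dt, n = 8000)
  ip_g <- g$h * as.numeric(crossprod(X, gfun))
  ip_h <- g$h * as.numeric(crossprod(X, hfun))
  emp <- mean(ip_g * ip_h)
  # <Q g, h> with Q diagonal in the retained basis
  cg <- g$h * crossprod(q$basis, gfun)
  ch <- g$h * crossprod(q$basis, hfun)
  theo <- dt * sum(lam * cg * ch)
  se <- stats::sd(ip_g * ip_h) / sqrt(8000)
  expect_lt(abs(emp - theo), 4 * se)
})

test_that("colored covariance reduces to the plain convolution law", {
  g <- grid_spec(1, 20, 256)
  phi <- smoothing_gaussian(1)
  qid <- q_spec(g, lambdas = rep(1, 255))
  cc <- colored_covariance(phi, qid, t = 1)
  tc <- theoretical_covariance(phi, 1, g)
  expect_lt(max(abs(cc$covariance - tc$covariance)), 1e-10)
  # zero smoothing: identically zero
  cz <- colored_covariance(smoothing_zero(), qid, t = 1)
  expect_equal(cz$covariance, rep(0, 256))
  # single-mode Q against a Monte Carlo oracle
  q1 <- q_spec(g, lambdas = 3)
  c1 <- colored_covariance(phi, q1, t = 1)
  set.seed(207)
  # noise = phi * (Q^(1/2) dW) simulated directly in the truncated basis
  R <- 4000
  xi <- matrix(stats::rnorm(R, sd = 1), 1, R)
  base <- sqrt(3) * q1$basis %*% xi
  sm <- grid_conv(g, smoothing_values(phi, g), base)
  i0 <- which(g$axis == 0)
  for (k in c(0, 8, 16)) {
    prods <- sm[i0, ] * sm[((i0 - 1 + k) %% g$M) + 1, ]
    d <- g$h * k
    theo <- c1$covariance[abs(c1$displacement - d) < 1e-9]
    se <- stats::sd(prods) / sqrt(R)
    expect_lt(abs(mean(prods) - theo), 5 * se)
  }
})
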