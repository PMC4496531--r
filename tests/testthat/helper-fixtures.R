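# fixtures shared across test files; everything is built in code

# homogeneous indicator kernel w(x, y) = 1{|x - y| <= a}
indicator_kernel <- function(a = 1) {
  snfield:::new_kernel(
    evaluate = function(x, y) as.numeric(abs(x - y) <= a),
    homogeneous = TRUE, symmetric = TRUE, analytic_l1 = 2 * a,
    profile = function(d) as.numeric(abs(d) <= a),
    length_scale = a, dim = 1L, label = "indicator")
}

# separable rank-one kernel w(x, y) = f(x) f(y); for f = exp(-x^2) the
# operator Jh = f <f, h> has spectral radius ||f||_{L2}^2 = sqrt(pi/2)
rank_one_kernel <- function(f = function(x) exp(-x^2)) {
  snfield:::new_kernel(
    evaluate = function(x, y) f(x) * f(y),
    homogeneous = FALSE, symmetric = TRUE, analytic_l1 = NA_real_,
    profile = NULL, length_scale = 1, dim = 1L, label = "rank one")
}

# separable Gaussian-product kernel w(x, y) = exp(-x^2 - y^2): C2 holds
gaussian_product_kernel <- function() {
  snfield:::new_kernel(
    evaluate = function(x, y) exp(-x^2 - y^2),
    homogeneous = FALSE, symmetric = TRUE, analytic_l1 = NA_real_,
    profile = NULL, length_scale = 1, dim = 1L,
    label = "gaussian product")
}

# run the exponential Euler recursion on supplied frozen noise,
# returning the full path matrix (a test-side re-implementation used
# to compare schemes on shared draws)
euler_path <- function(Y0, dt, n_steps, kernel, gain, diffusion, phi,
                       grid, noise) {
  path <- matrix(0, n_steps + 1, grid$n_nodes)
  path[1, ] <- Y0
  Y <- Y0
  for (n in seq_len(n_steps)) {
    dW <- noise[, n]
    attr(dW, "dt") <- dt
    Y <- step_exponential_euler(Y, dt, kernel, gain, diffusion, phi,
                                grid, dW)
    path[n + 1, ] <- Y
  }
  path
}

# coarsen fine-step white-noise increments by dyadic summation so the
# same underlying realization drives runs at several resolutions
coarsen_noise <- function(noise, fac) {
  ns <- ncol(noise) / fac
  out <- sapply(seq_len(ns), function(m) {
    rowSums(noise[, ((m - 1) * fac + 1):(m * fac), drop = FALSE])
  })
  attr(out, "dt") <- attr(noise, "dt") * fac
  out
}
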