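#' @title Neural field connectivity kernels
#' @name kernels
#' @description
#' Constructors for the connectivity kernels \eqn{w(x, y)} commonly used
#' in neural field models.  A kernel object evaluates the synaptic weight
#' density between pairs of points and records whether it is homogeneous
#' (a function of \eqn{x - y} only), symmetric, and, where a closed form
#' exists, the exact value of \eqn{\sup_x \|w(x,\cdot)\|_{L^1}}.
NULL

new_kernel <- function(evaluate, homogeneous, symmetric,
                       analytic_l1 = NA_real_, profile = NULL,
                       length_scale = 1, dim = NA_integer_,
                       label = "kernel") {
  structure(
    list(evaluate = evaluate, homogeneous = homogeneous,
         symmetric = symmetric, analytic_l1 = analytic_l1,
         profile = profile, length_scale = length_scale,
         dim = dim, label = label, cache = new.env(parent = emptyenv())),
    class = "nf_kernel")
}

#' @export
print.nf_kernel <- function(x, ...) {
  cat(sprintf("<nf_kernel> %s (%s%s)\n", x$label,
              if (x$homogeneous) "homogeneous" else "non-homogeneous",
              if (!is.na(x$analytic_l1))
                sprintf(", sup-L1 norm = %g", x$analytic_l1) else ""))
  invisible(x)
}

# row-wise Euclidean distance between point sets given as vectors (N=1)
# or matrices with one row per point (N=2)
pair_dist <- function(x, y) {
  if (is.matrix(x) || is.matrix(y)) {
    x <- rbind(x); y <- rbind(y)
    sqrt(rowSums((x - y)^2))
  } else {
    abs(x - y)
  }
}

#' Gaussian (local connectivity) kernel
#'
#' The isotropic homogeneous kernel
#' \eqn{w(x, y) = K \exp(-|x-y|^2 / 2\beta^2)} modelling local synaptic
#' connections, with amplitude \code{K} and connectivity extent
#' \code{beta}.  Its exact \eqn{L^1} norm is
#' \eqn{K (2\pi)^{N/2} \beta^N}.
#'
#' @param K amplitude (> 0).
#' @param beta connectivity length scale (> 0).
#' @param N spatial dimension the closed-form norm refers to (1 or 2).
#' @return An \code{nf_kernel}.
#' @examples
#' w <- gaussian_kernel(K = 1, beta = 1)
#' w$evaluate(0, 2)  # exp(-2)
#' @export
gaussian_kernel <- function(K = 1, beta = 1, N = 1) {
  if (K <= 0 || beta <= 0) stop("K and beta must be positive")
  prof <- function(d) K * exp(-d^2 / (2 * beta^2))
  new_kernel(
    evaluate = function(x, y) prof(pair_dist(x, y)),
    homogeneous = TRUE, symmetric = TRUE,
    analytic_l1 = K * (2 * pi)^(N / 2) * beta^N,
    profile = function(d) prof(pair_dist(d, if (is.matrix(d)) d * 0 else 0)),
    length_scale = beta, dim = N,
    label = sprintf("gaussian(K=%g, beta=%g)", K, beta))
}

#' Mexican hat kernel
#'
#' Difference of two Gaussians,
#' \eqn{w(x,y) = K_1 e^{-|x-y|^2/2\beta_1^2} - K_2 e^{-|x-y|^2/2\beta_2^2}},
#' modelling local excitation with surround inhibition when
#' \eqn{\beta_2 > \beta_1} and \eqn{K_1 > K_2}.  The recorded
#' \code{analytic_l1} is the \eqn{L^1} norm of \eqn{|w|}: when the two
#' Gaussians never cross it is the closed-form
#' \eqn{|K_1\beta_1^N - K_2\beta_2^N| (2\pi)^{N/2}}; when a sign change
#' exists it is computed exactly via the error function for \eqn{N = 1}
#' and by quadrature otherwise.
#'
#' @param K1,K2 amplitudes (> 0).
#' @param beta1,beta2 length scales (> 0).
#' @param N spatial dimension (1 or 2).
#' @return An \code{nf_kernel} with \code{w(x,x) = K1 - K2}.
#' @export
mexican_hat_kernel <- function(K1 = 2, K2 = 1, beta1 = 1, beta2 = 2, N = 1) {
  if (any(c(K1, K2, beta1, beta2) <= 0)) stop("all parameters must be positive")
  prof <- function(d) K1 * exp(-d^2 / (2 * beta1^2)) -
    K2 * exp(-d^2 / (2 * beta2^2))
  l1 <- mexican_hat_l1(K1, K2, beta1, beta2, N)
  new_kernel(
    evaluate = function(x, y) prof(pair_dist(x, y)),
    homogeneous = TRUE, symmetric = TRUE,
    analytic_l1 = l1,
    profile = function(d) prof(pair_dist(d, if (is.matrix(d)) d * 0 else 0)),
    length_scale = max(beta1, beta2), dim = N,
    label = sprintf("mexican_hat(K1=%g, K2=%g, beta1=%g, beta2=%g)",
                    K1, K2, beta1, beta2))
}

# L1 norm of |K1 G_{beta1} - K2 G_{beta2}| (unnormalized Gaussians)
mexican_hat_l1 <- function(K1, K2, beta1, beta2, N) {
  if (beta1 == beta2) {
    return(abs(K1 - K2) * (2 * pi)^(N / 2) * beta1^N)
  }
  a <- 1 / (2 * beta1^2) - 1 / (2 * beta2^2)
  lr <- log(K1 / K2)
  # sign change at |u| = u0 where K1 e^{-u^2/2b1^2} = K2 e^{-u^2/2b2^2}
  u0sq <- lr / a
  if (!is.finite(u0sq) || u0sq <= 0) {
    # no crossing: |integral of w| is the norm
    return(abs(K1 * beta1^N - K2 * beta2^N) * (2 * pi)^(N / 2))
  }
  u0 <- sqrt(u0sq)
  if (N == 1) {
    # int_0^a K e^{-u^2/2b^2} du = K b sqrt(pi/2) erf(a/(b sqrt(2)))
    half <- function(K, b) {
      inner <- K * b * sqrt(pi / 2) * pracma::erf(u0 / (b * sqrt(2)))
      total <- K * b * sqrt(pi / 2)
      c(inner = inner, outer = total - inner)
    }
    g1 <- half(K1, beta1); g2 <- half(K2, beta2)
    # |w| integrates w inside the crossing and -w outside (or vice versa)
    unname(2 * abs(g1["inner"] - g2["inner"]) +
             2 * abs(g1["outer"] - g2["outer"]))
  } else {
    f <- function(r) abs(K1 * exp(-r^2 / (2 * beta1^2)) -
                           K2 * exp(-r^2 / (2 * beta2^2))) * 2 * pi * r
    stats::integrate(f, 0, Inf, rel.tol = 1e-12)$value
  }
}

#' Exponential (Laplacian-profile) connectivity kernel
#'
#' The homogeneous kernel \eqn{w(x,y) = (2\beta)^{-1} e^{-|x-y|/\beta}}
#' in one dimension, normalized so that \eqn{\|w(x,\cdot)\|_{L^1} = 1}
#' for every \eqn{x}.
#'
#' @param beta connectivity range (> 0).
#' @return An \code{nf_kernel} with \code{analytic_l1 = 1}.
#' @export
exponential_kernel <- function(beta = 1) {
  if (beta <= 0) stop("beta must be positive")
  prof <- function(d) exp(-d / beta) / (2 * beta)
  new_kernel(
    evaluate = function(x, y) prof(pair_dist(x, y)),
    homogeneous = TRUE, symmetric = TRUE,
    analytic_l1 = 1,
    profile = function(d) prof(abs(d)),
    length_scale = beta, dim = 1L,
    label = sprintf("exponential(beta=%g)", beta))
}

#' Anisotropy factor for long-range connectivity
#'
#' \eqn{A(\chi, x) = \exp[-((1-\chi)^2 x_1^2 + x_2^2)/2\beta_{lr}^2]}
#' for a two-dimensional displacement \eqn{x = (x_1, x_2)}.  With
#' \eqn{\chi = 0} the factor is isotropic (it depends on \eqn{|x|} only);
#' \eqn{\chi \in (0, 1)} stretches the connectivity along the first axis,
#' modelling species whose long-range connections align with the
#' preferred orientation.
#'
#' @param chi anisotropy parameter in \eqn{[0, 1)}.
#' @param x a 2-vector or a matrix of row displacements.
#' @param beta_lr extent of long-range connectivity (> 0).
#' @return Values in \eqn{(0, 1]}.
#' @export
anisotropy_factor <- function(chi, x, beta_lr = 1) {
  if (chi < 0 || chi >= 1) stop("chi must lie in [0, 1)")
  if (beta_lr <= 0) stop("beta_lr must be positive")
  x <- rbind(x)
  as.numeric(exp(-((1 - chi)^2 * x[, 1]^2 + x[, 2]^2) / (2 * beta_lr^2)))
}

#' Synthetic cortical orientation map
#'
#' Generates a smooth preferred-orientation map
#' \eqn{\theta(x) \in [0, \pi)} on a two-dimensional grid as the
#' half-argument of a superposition of complex plane waves with random
#' directions and phases, the standard construction for model cortical
#' maps.  Pinwheels (singularities of \eqn{\theta}) sit at the zeros of
#' the underlying complex field; nodes landing numerically on a zero are
#' perturbed so \eqn{\theta} is defined everywhere.
#'
#' @param grid an \code{nf_grid} with \code{N = 2}.
#' @param n_modes number of plane waves.  With \code{n_modes = 1} the map
#'   is a perfect linear gradient (no pinwheels); more modes produce a
#'   quasi-periodic map with pinwheels.
#' @param seed integer seed making the map reproducible.
#' @return An object of class \code{nf_orientation_map}: list with
#'   \code{theta} (values in \eqn{[0, \pi)} at each grid node),
#'   \code{theta_fun} (nearest-node lookup function), and
#'   \code{pinwheel_centers} (nodes where the complex field magnitude has
#'   a local minimum near zero).
#' @export
orientation_map_synthetic <- function(grid, n_modes = 8, seed = 1) {
  if (grid$N != 2L) stop("orientation maps require a 2D grid")
  nodes <- grid_nodes(grid)
  kmag <- 2 * pi / (2 * grid$L)  # fundamental wavenumber, periodic modes
  if (n_modes <= 1) {
    z <- exp(1i * kmag * nodes[, 1])
  } else {
    set.seed(seed)
    # integer wavevectors on a ring keep the field exactly periodic
    ang <- stats::runif(n_modes, 0, 2 * pi)
    ring <- max(1L, round(sqrt(n_modes)))
    kx <- round(ring * cos(ang)); ky <- round(ring * sin(ang))
    keep <- !(kx == 0 & ky == 0)
    kx <- kx[keep]; ky <- ky[keep]
    ph <- stats::runif(length(kx), 0, 2 * pi)
    amp <- stats::rnorm(length(kx))^2 + 0.1
    z <- rep(0 + 0i, nrow(nodes))
    for (j in seq_along(kx)) {
      z <- z + amp[j] * exp(1i * (kmag * (kx[j] * nodes[, 1] +
                                            ky[j] * nodes[, 2]) + ph[j]))
    }
  }
  mag <- Mod(z)
  z[mag < 1e-12] <- z[mag < 1e-12] + 1e-10  # perturb exact zeros off-center
  theta <- (Arg(z) / 2) %% pi
  # pinwheel candidates: magnitude below the 2% quantile and a local min
  pin <- NULL
  if (n_modes > 1) {
    magm <- matrix(mag, grid$M, grid$M)
    thr <- stats::quantile(mag, 0.02)
    idx <- which(magm <= thr, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      keep <- vapply(seq_len(nrow(idx)), function(r) {
        i <- idx[r, 1]; j <- idx[r, 2]
        nb <- magm[cbind(((i + c(-1, 1, 0, 0) - 1) %% grid$M) + 1,
                         ((j + c(0, 0, -1, 1) - 1) %% grid$M) + 1)]
        all(magm[i, j] <= nb)
      }, logical(1))
      idx <- idx[keep, , drop = FALSE]
      pin <- cbind(grid$axis[idx[, 1]], grid$axis[idx[, 2]])
    }
  }
  lookup <- function(x) {
    x <- rbind(x)
    i <- pmin(pmax(round((x[, 1] + grid$L) / grid$h) + 1, 1), grid$M)
    j <- pmin(pmax(round((x[, 2] + grid$L) / grid$h) + 1, 1), grid$M)
    theta[(j - 1) * grid$M + i]
  }
  structure(list(theta = theta, theta_fun = lookup,
                 pinwheel_centers = pin, grid = grid, seed = seed),
            class = "nf_orientation_map")
}

#' Anisotropic long-range connectivity kernel
#'
#' The patchy long-range kernel of primary visual cortex models,
#' \deqn{w_{lr}(x, y) = \varepsilon_{lr}\, A(\chi, R_{-2\theta(x)}(x-y))
#'   \; G_{\beta_\theta}(\theta(x) - \theta(y)),}
#' where \eqn{R_\alpha} is rotation by \eqn{\alpha}, \eqn{A} the
#' anisotropy factor and \eqn{G_{\beta_\theta}} the one-dimensional
#' Gaussian density with mean 0 and standard deviation
#' \eqn{\beta_\theta}.  Because \eqn{\theta(x) - \theta(y)} is not a
#' function of \eqn{x - y}, the kernel is not homogeneous (unless
#' \eqn{\theta} is constant and \eqn{\chi = 0}).
#'
#' @param eps_lr long-range amplitude (typically much less than 1).
#' @param chi anisotropy in \eqn{[0, 1)}.
#' @param beta_lr long-range extent (> 0).
#' @param beta_theta orientation tuning width (> 0).
#' @param theta_map an \code{nf_orientation_map}, or a single number for
#'   a constant orientation preference.
#' @return An \code{nf_kernel} (non-homogeneous in general;
#'   flagged homogeneous for constant \code{theta_map} with
#'   \code{chi = 0}).
#' @export
long_range_kernel <- function(eps_lr = 0.1, chi = 0, beta_lr = 2,
                              beta_theta = pi / 8, theta_map = NULL) {
  if (is.null(theta_map)) stop("an orientation map is required")
  if (beta_lr <= 0 || beta_theta <= 0) stop("length scales must be positive")
  if (chi < 0 || chi >= 1) stop("chi must lie in [0, 1)")
  const_theta <- is.numeric(theta_map) && length(theta_map) == 1L
  tfun <- if (const_theta) {
    th0 <- theta_map
    function(x) rep(th0, nrow(rbind(x)))
  } else theta_map$theta_fun
  gdens <- function(d) exp(-d^2 / (2 * beta_theta^2)) /
    (sqrt(2 * pi) * beta_theta)
  evaluate <- function(x, y) {
    x <- rbind(x); y <- rbind(y)
    tx <- tfun(x); ty <- tfun(y)
    d <- x - y
    a <- -2 * tx  # rotate displacement by -2 theta(x)
    rd <- cbind(cos(a) * d[, 1] - sin(a) * d[, 2],
                sin(a) * d[, 1] + cos(a) * d[, 2])
    as.numeric(eps_lr * anisotropy_factor(chi, rd, beta_lr) *
                 gdens(tx - ty))
  }
  homog <- const_theta && chi == 0
  prof <- if (homog) {
    g0 <- gdens(0)
    function(d) {
      d <- rbind(d)
      eps_lr * g0 * exp(-rowSums(d^2) / (2 * beta_lr^2))
    }
  } else NULL
  new_kernel(evaluate = evaluate, homogeneous = homog, symmetric = homog,
             analytic_l1 = NA_real_, profile = prof,
             length_scale = beta_lr, dim = 2L,
             label = sprintf("long_range(eps=%g, chi=%g)", eps_lr, chi))
}

#' Combined local plus long-range kernel
#'
#' Pointwise sum \eqn{w(x,y) = w_{loc}(x-y) + w_{lr}(x,y)} used for the
#' primary visual area.  The sum is homogeneous only when both parts are.
#'
#' @param local,longrange \code{nf_kernel} objects on the same dimension.
#' @return An \code{nf_kernel}.
#' @export
pva_kernel <- function(local, longrange) {
  stopifnot(inherits(local, "nf_kernel"), inherits(longrange, "nf_kernel"))
  if (!is.na(local$dim) && !is.na(longrange$dim) &&
      local$dim != longrange$dim) {
    stop("kernels are defined on different dimensions")
  }
  homog <- local$homogeneous && longrange$homogeneous
  prof <- if (homog) function(d) local$profile(d) + longrange$profile(d)
  else NULL
  new_kernel(
    evaluate = function(x, y) local$evaluate(x, y) + longrange$evaluate(x, y),
    homogeneous = homog,
    symmetric = local$symmetric && longrange$symmetric,
    analytic_l1 = NA_real_, profile = prof,
    length_scale = max(local$length_scale, longrange$length_scale),
    dim = if (!is.na(local$dim)) local$dim else longrange$dim,
    label = sprintf("pva(%s + %s)", local$label, longrange$label))
}

#' Zero kernel
#'
#' Convenience kernel with \eqn{w \equiv 0}; the drift vanishes and the
#' equation decouples into independent noisy decay at every node.
#' @return An \code{nf_kernel}.
#' @export
zero_kernel <- function() {
  new_kernel(evaluate = function(x, y) rep(0, length(pair_dist(x, y))),
             homogeneous = TRUE, symmetric = TRUE, analytic_l1 = 0,
             profile = function(d) {
               rep(0, if (is.matrix(d)) nrow(d) else length(d))
             },
             length_scale = 1, dim = NA_integer_, label = "zero")
}

#' Homogeneous kernel profile on the displacement nodes
#'
#' Tabulates \eqn{w(d)} on the grid's wrapped displacement nodes (FFT
#' order), the form consumed by the FFT convolution drift.  Cached per
#' grid on the kernel object.
#'
#' @param kernel a homogeneous \code{nf_kernel}.
#' @param grid an \code{nf_grid}.
#' @return Numeric vector of length \code{M^N}.
#' @export
kernel_profile <- function(kernel, grid) {
  if (!kernel$homogeneous) stop("profiles exist only for homogeneous kernels")
  key <- sprintf("prof_%g_%d_%d", grid$L, grid$M, grid$N)
  if (!is.null(kernel$cache[[key]])) return(kernel$cache[[key]])
  d <- grid_displacements(grid)
  v <- as.numeric(kernel$profile(d))
  kernel$cache[[key]] <- v
  v
}

#' Dense kernel matrix on a grid
#'
#' Matrix \eqn{W_{ij} = w(x_i, y_j)} over all node pairs, used for the
#' dense drift path and the power-iteration weight construction.  For
#' homogeneous kernels the displacement is wrapped periodically so the
#' matrix represents the same operator as the FFT convolution; for
#' non-homogeneous kernels the pairs are evaluated at their actual
#' coordinates (truncated quadrature).  Cached.
#'
#' @inheritParams kernel_profile
#' @param absolute take \eqn{|w|}? Default \code{FALSE}.
#' @return \code{M^N} by \code{M^N} matrix; rows index the target point
#'   \eqn{x}, columns the source point \eqn{y}.
#' @export
kernel_matrix <- function(kernel, grid, absolute = FALSE) {
  key <- sprintf("mat_%g_%d_%d_%d", grid$L, grid$M, grid$N, absolute)
  if (!is.null(kernel$cache[[key]])) return(kernel$cache[[key]])
  nodes <- grid_nodes(grid)
  n <- grid$n_nodes
  wrap <- function(d) ((d + grid$L) %% (2 * grid$L)) - grid$L
  if (kernel$homogeneous) {
    W <- matrix(0, n, n)
    if (grid$N == 1L) {
      for (j in seq_len(n)) {
        W[, j] <- kernel$profile(wrap(nodes - nodes[j]))
      }
    } else {
      for (j in seq_len(n)) {
        W[, j] <- kernel$profile(cbind(wrap(nodes[, 1] - nodes[j, 1]),
                                       wrap(nodes[, 2] - nodes[j, 2])))
      }
    }
  } else if (grid$N == 1L) {
    W <- outer(seq_len(n), seq_len(n),
               function(i, j) kernel$evaluate(nodes[i], nodes[j]))
  } else {
    W <- matrix(0, n, n)
    for (j in seq_len(n)) {
      W[, j] <- kernel$evaluate(nodes, matrix(nodes[j, ], n, 2, byrow = TRUE))
    }
  }
  if (absolute) W <- abs(W)
  kernel$cache[[key]] <- W
  W
}

#' Sigmoid gain function
#'
#' The logistic gain \eqn{G(a) = (1 + e^{-a})^{-1}}, bounded by 1 and
#' globally Lipschitz; the sharpest slope is \eqn{1/4}, attained at 0.
#'
#' @return An object of class \code{nf_gain} with fields \code{apply},
#'   \code{bound} (\eqn{C_G = 1}) and \code{slope_bound} (1/4).
#' @export
sigmoid_gain <- function() {
  structure(list(apply = function(a) 1 / (1 + exp(-a)),
                 bound = 1, lipschitz = 1, slope_bound = 0.25,
                 label = "sigmoid"),
            class = "nf_gain")
}

#' Constant gain function
#'
#' \eqn{G \equiv c}; with \eqn{c = 0} the drift reduces to pure decay.
#' @param c the constant value.
#' @return An \code{nf_gain}.
#' @export
constant_gain <- function(c = 0) {
  structure(list(apply = function(a) rep(c, length(a)),
                 bound = abs(c), lipschitz = 0, slope_bound = 0,
                 label = sprintf("constant(%g)", c)),
            class = "nf_gain")
}

#' Linear diffusion coefficient
#'
#' Multiplicative noise \eqn{\sigma(a) = \lambda a}: the noise amplitude
#' scales with the local activity.  Lipschitz and of linear growth with
#' constant \eqn{|\lambda|}.
#'
#' @param lambda slope.
#' @return An object of class \code{nf_diffusion} with fields
#'   \code{apply}, \code{lipschitz}, \code{linear_growth}, \code{lambda}.
#' @export
linear_diffusion <- function(lambda = 1) {
  structure(list(apply = function(a) lambda * a,
                 lipschitz = abs(lambda), linear_growth = abs(lambda),
                 lambda = lambda, label = sprintf("linear(%g)", lambda)),
            class = "nf_diffusion")
}

#' Constant diffusion coefficient
#'
#' Additive noise \eqn{\sigma \equiv c}; \eqn{c = 1} gives the purely
#' additive smoothed-noise equation, \eqn{c = 0} switches the noise off.
#' @param c the constant value.
#' @return An \code{nf_diffusion}.
#' @export
constant_diffusion <- function(c = 1) {
  structure(list(apply = function(a) rep(c, length(a)),
                 lipschitz = 0, linear_growth = abs(c), lambda = NA_real_,
                 label = sprintf("constant(%g)", c)),
            class = "nf_diffusion")
}

#' Bounded smooth diffusion coefficient
#'
#' \eqn{\sigma(a) = c \tanh(a)}: Lipschitz with constant \code{c} and
#' bounded by \code{c}, convenient for moment-boundedness experiments.
#' @param c amplitude.
#' @return An \code{nf_diffusion}.
#' @export
tanh_diffusion <- function(c = 1) {
  structure(list(apply = function(a) c * tanh(a),
                 lipschitz = abs(c), linear_growth = abs(c),
                 lambda = NA_real_, label = sprintf("tanh(%g)", c)),
            class = "nf_diffusion")
}
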