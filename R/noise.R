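#' @title Space-time white noise, smoothed noise and Q-Wiener processes
#' @name noise
#' @description
#' The driving noises of the stochastic neural field equation.  Set-
#' indexed space-time white noise is represented by independent centered
#' Gaussian cell increments with variance \eqn{\Delta t \, h^N} (the
#' Lebesgue measure of a space-time cell), so that the covariance of the
#' increment over cell unions \eqn{A, B} is \eqn{|A \cap B|}.  Spatial
#' smoothing by a square-integrable kernel \eqn{\varphi} produces the
#' correlated field \eqn{W^\varphi} whose spatial covariance at time
#' \eqn{t} is \eqn{t\,(\varphi \star \tilde\varphi)(x - y)}; truncated
#' Karhunen-Loeve expansions give Q-Wiener increments.
NULL

#' Smoothing (spatial correlation) kernels
#'
#' Constructors for the smoothing function \eqn{\varphi \in L^2} that
#' colors the noise in space.  Each returns an object of class
#' \code{nf_smoothing} holding the analytic function, its values on a
#' grid's displacement nodes, the exact \eqn{L^2} norm where a closed
#' form exists, and (when known) the shift-modulus exponent
#' \eqn{\alpha} such that
#' \eqn{\|\varphi - \tau_z \varphi\|_{L^2} \le C_\varphi |z|^\alpha}:
#' \eqn{\alpha = 1} for the Gaussian (a Sobolev \eqn{W^{1,2}} function)
#' and \eqn{\alpha = 1/2} for the indicator.
#'
#' @param amplitude multiplicative amplitude.
#' @param beta Gaussian width (space units).
#' @param halfwidth half-width of the indicator support
#'   \eqn{[-a, a]}.
#' @param fun arbitrary function of the displacement for
#'   \code{smoothing_custom}.
#' @param l2_norm,shift_alpha optional analytic metadata for custom
#'   kernels.
#' @return An \code{nf_smoothing}.
#' @name smoothing
NULL

# coerce displacements to a points-in-rows matrix: a bare numeric vector
# is a set of 1D points, never a single N-D point
as_points <- function(d) if (is.matrix(d)) d else matrix(d, ncol = 1)

new_smoothing <- function(fun, form, l2_norm = NA_real_,
                          shift_alpha = NA_real_, label = form) {
  structure(list(fun = fun, form = form, l2_norm = l2_norm,
                 shift_alpha = shift_alpha, label = label,
                 cache = new.env(parent = emptyenv())),
            class = "nf_smoothing")
}

#' @rdname smoothing
#' @export
smoothing_gaussian <- function(beta = 1, amplitude = 1) {
  if (beta <= 0) stop("beta must be positive")
  new_smoothing(
    fun = function(d) amplitude * exp(-rowSums(as_points(d)^2) /
                                        (2 * beta^2)),
    form = "gaussian",
    l2_norm = abs(amplitude) * (pi * beta^2)^(1 / 4) * sqrt(1),  # N = 1
    shift_alpha = 1,
    label = sprintf("gaussian(beta=%g)", beta))
}

#' @rdname smoothing
#' @export
smoothing_indicator <- function(halfwidth = 0.5, amplitude = 1) {
  if (halfwidth <= 0) stop("halfwidth must be positive")
  new_smoothing(
    fun = function(d) amplitude * (sqrt(rowSums(as_points(d)^2)) <=
                                     halfwidth),
    form = "indicator",
    l2_norm = abs(amplitude) * sqrt(2 * halfwidth),  # N = 1
    shift_alpha = 0.5,
    label = sprintf("indicator(a=%g)", halfwidth))
}

#' @rdname smoothing
#' @export
smoothing_custom <- function(fun, l2_norm = NA_real_,
                             shift_alpha = NA_real_) {
  new_smoothing(fun = fun, form = "custom", l2_norm = l2_norm,
                shift_alpha = shift_alpha, label = "custom")
}

#' @rdname smoothing
#' @export
smoothing_zero <- function() {
  new_smoothing(fun = function(d) rep(0, nrow(as_points(d))), form = "zero",
                l2_norm = 0, shift_alpha = NA_real_, label = "zero")
}

#' @export
print.nf_smoothing <- function(x, ...) {
  cat(sprintf("<nf_smoothing> %s (L2 norm %s, shift exponent %s)\n",
              x$label,
              if (is.na(x$l2_norm)) "unknown" else signif(x$l2_norm, 6),
              if (is.na(x$shift_alpha)) "unknown" else x$shift_alpha))
  invisible(x)
}

#' Smoothing kernel values on the displacement nodes
#'
#' Tabulates \eqn{\varphi} on the grid's wrapped displacements (FFT
#' order) and warns when a noticeable fraction of its mass lies outside
#' \eqn{|x| > L/4}, in which case the periodic truncation distorts the
#' covariance.  Cached per grid.
#'
#' @param phi an \code{nf_smoothing}.
#' @param grid an \code{nf_grid}.
#' @return Numeric vector of length \code{M^N}.
#' @export
smoothing_values <- function(phi, grid) {
  key <- sprintf("val_%g_%d_%d", grid$L, grid$M, grid$N)
  if (!is.null(phi$cache[[key]])) return(phi$cache[[key]])
  d <- grid_displacements(grid)
  v <- as.numeric(phi$fun(d))
  dist <- if (grid$N == 1L) abs(d) else sqrt(rowSums(d^2))
  total <- sum(v^2)
  if (total > 0) {
    outer_mass <- sum(v[dist > grid$L / 4]^2) / total
    if (outer_mass > 1e-8) {
      warning(sprintf(paste("smoothing kernel carries %.2g of its squared",
                            "mass beyond L/4; enlarge the box"), outer_mass))
    }
  }
  phi$cache[[key]] <- v
  v
}

#' Discrete L2 norm of a smoothing kernel on a grid
#'
#' @inheritParams smoothing_values
#' @export
smoothing_l2 <- function(phi, grid) {
  grid_l2_norm(grid, smoothing_values(phi, grid))
}

#' White-noise increments over one time step
#'
#' Independent centered Gaussian masses, one per grid cell, with
#' variance \eqn{\Delta t \, h^N}; sums over disjoint cell unions then
#' have the set-indexed white-noise covariance \eqn{|A \cap B|}.
#'
#' @param grid an \code{nf_grid}.
#' @param dt time step (> 0).
#' @param n number of independent realizations; for \code{n > 1} a
#'   matrix with one column per realization is returned (1D grids).
#' @return Numeric vector of length \code{M^N} (or matrix
#'   \code{M^N x n}) with attribute \code{dt}.
#' @export
white_noise_increments <- function(grid, dt, n = 1) {
  if (dt <= 0) stop("dt must be positive")
  sd <- sqrt(dt * grid$cellvol)
  out <- if (n == 1) stats::rnorm(grid$n_nodes, sd = sd)
  else matrix(stats::rnorm(grid$n_nodes * n, sd = sd), grid$n_nodes, n)
  attr(out, "dt") <- dt
  out
}

#' Spatially smoothed noise increment
#'
#' \eqn{\Delta W^\varphi(x) = \sum_{\mathrm{cells}} \varphi(x - y_c)\,
#' \Delta W(c)}, a Riemann-sum approximation of the Walsh integral of
#' \eqn{\varphi(x - \cdot)}, computed as a circular FFT convolution.
#' Linear in the white noise; the pointwise variance is
#' \eqn{\Delta t \sum_c \varphi(x - y_c)^2 h^N \approx \Delta t\,
#' \|\varphi\|_{L^2}^2}.
#'
#' @param white increments from [white_noise_increments()] (vector or
#'   one column per realization).
#' @param phi an \code{nf_smoothing}.
#' @param grid the grid the increments were drawn on.
#' @return Smoothed field(s), same shape as \code{white}.
#' @export
smoothed_increment <- function(white, phi, grid) {
  if ((if (is.matrix(white)) nrow(white) else length(white)) !=
      grid$n_nodes) {
    stop("white-noise increments do not match the grid")
  }
  v <- smoothing_values(phi, grid)
  out <- grid_conv(grid, v, white, cellvol = FALSE)
  attr(out, "dt") <- attr(white, "dt")
  out
}

#' Theoretical spatial covariance of the smoothed noise field
#'
#' The exact covariance of \eqn{W^\varphi(t, \cdot)} as a function of
#' displacement: \eqn{c(r) = t (\varphi \star \tilde\varphi)(r)}, with
#' \eqn{\tilde\varphi(x) = \varphi(-x)}, computed by FFT on the periodic
#' grid.  Symmetric in \eqn{r}, maximal at 0 where it equals
#' \eqn{t \|\varphi\|_{L^2}^2}.
#'
#' @param phi an \code{nf_smoothing}.
#' @param t time (>= 0).
#' @param grid an \code{nf_grid}.
#' @return Data frame with columns \code{displacement} (sorted
#'   ascending) and \code{covariance}.
#' @export
theoretical_covariance <- function(phi, t, grid) {
  if (t < 0) stop("t must be nonnegative")
  v <- smoothing_values(phi, grid)
  fa <- field_as_array(grid, v)
  ac <- Re(stats::fft(stats::fft(fa) * Conj(stats::fft(fa)),
                      inverse = TRUE)) / grid$n_nodes * grid$cellvol
  ac <- as.numeric(ac) * t
  d <- grid_displacements(grid)
  if (grid$N == 1L) {
    ord <- order(d)
    data.frame(displacement = d[ord], covariance = ac[ord])
  } else {
    data.frame(displacement = sqrt(rowSums(d^2)), covariance = ac)
  }
}

#' Shift modulus of a smoothing kernel
#'
#' \eqn{\|\varphi - \tau_z \varphi\|_{L^2}} for a grid-commensurate
#' shift \eqn{z} (\eqn{\tau_z \varphi(y) = \varphi(y + z)}), by
#' cell-weighted quadrature on the periodic grid.  The power-law
#' exponent of the modulus in \eqn{|z|} governs the spatial Hölder
#' regularity of \eqn{W^\varphi}.
#'
#' @param phi an \code{nf_smoothing}.
#' @param z shift; must be an integer multiple of the grid spacing
#'   (1D grids).
#' @param grid an \code{nf_grid}.
#' @return The modulus (numeric scalar).
#' @export
shift_modulus <- function(phi, z, grid) {
  stopifnot(grid$N == 1L)
  k <- z / grid$h
  if (abs(k - round(k)) > 1e-9) {
    stop("shift must be an integer multiple of the grid spacing")
  }
  k <- round(k) %% grid$M
  v <- smoothing_values(phi, grid)
  shifted <- v[(((0:(grid$M - 1)) + k) %% grid$M) + 1]
  grid_l2_norm(grid, v - shifted)
}

#' Truncated Q-Wiener specification
#'
#' A trace-class covariance operator \eqn{Q} given by its (truncated)
#' eigen-expansion: nonnegative eigenvalues \eqn{\lambda_k} and
#' orthonormal eigenfunctions \eqn{e_k} on the grid.  The default basis
#' is the real Fourier basis (constant, cosine and sine pairs at the
#' grid's natural frequencies), in which stationary covariances are
#' diagonal.
#'
#' @param grid an \code{nf_grid} with \code{N = 1}.
#' @param lambdas nonnegative eigenvalues, one per retained mode.
#' @param basis either \code{"fourier"} or a matrix with one
#'   orthonormal eigenfunction per column (discrete inner product
#'   \eqn{h \sum e_j e_k = \delta_{jk}}).
#' @return An object of class \code{nf_qspec} with \code{lambdas},
#'   \code{basis} (matrix \code{M x k_max}), \code{trace} and the
#'   reported truncation \code{tail} (always 0 for an explicit finite
#'   spectrum).
#' @export
q_spec <- function(grid, lambdas, basis = "fourier") {
  stopifnot(grid$N == 1L)
  if (any(lambdas < 0)) stop("Q eigenvalues must be nonnegative")
  k_max <- length(lambdas)
  if (k_max < 1) stop("at least one mode is required")
  if (is.character(basis) && basis == "fourier") {
    if (k_max > grid$M - 1) {
      stop("the grid resolves at most M - 1 Fourier modes")
    }
    B <- fourier_basis(grid, k_max)
  } else {
    B <- as.matrix(basis)
    if (ncol(B) < k_max) stop("basis has fewer columns than eigenvalues")
    B <- B[, seq_len(k_max), drop = FALSE]
  }
  G <- grid$cellvol * crossprod(B)
  if (max(abs(G - diag(k_max))) > 1e-10) {
    stop("eigenfunctions are not orthonormal on the grid")
  }
  structure(list(lambdas = lambdas, basis = B, k_max = k_max,
                 trace = sum(lambdas), tail = 0, grid = grid),
            class = "nf_qspec")
}

# real Fourier basis: 1/sqrt(2L), then cos/sin pairs, orthonormal in
# the cell-weighted inner product
fourier_basis <- function(grid, k_max) {
  x <- grid$axis
  L <- grid$L
  B <- matrix(0, grid$M, k_max)
  B[, 1] <- 1 / sqrt(2 * L)
  j <- 1
  k <- 2
  while (k <= k_max) {
    B[, k] <- cos(pi * j * x / L) / sqrt(L)
    if (k + 1 <= k_max) B[, k + 1] <- sin(pi * j * x / L) / sqrt(L)
    k <- k + 2
    j <- j + 1
  }
  B
}

#' Q-Wiener process increment
#'
#' \eqn{\Delta W = \sum_{k \le k_{max}} \sqrt{\lambda_k}\, \xi_k e_k}
#' with independent \eqn{\xi_k \sim N(0, \Delta t)}: the truncated
#' Karhunen-Loeve sample of a Q-Wiener increment.  Projections onto
#' distinct eigenfunctions are uncorrelated with variances
#' \eqn{\lambda_k \Delta t}.
#'
#' @param q an \code{nf_qspec}.
#' @param dt time step (> 0).
#' @param n number of independent realizations.
#' @return Field vector (or \code{M x n} matrix) with attribute
#'   \code{dt}.
#' @export
q_wiener_increment <- function(q, dt, n = 1) {
  if (dt <= 0) stop("dt must be positive")
  xi <- matrix(stats::rnorm(q$k_max * n, sd = sqrt(dt)), q$k_max, n)
  out <- q$basis %*% (sqrt(q$lambdas) * xi)
  if (n == 1) out <- as.numeric(out)
  attr(out, "dt") <- dt
  out
}

#' Spatial covariance of Q-colored smoothed noise
#'
#' The covariance function
#' \eqn{c = (Q^{1/2}\varphi) \star (Q^{1/2}\varphi)\tilde{}} of noise
#' that is smoothed by \eqn{\varphi} and colored by a diagonal-in-
#' Fourier \eqn{Q}.  When every retained eigenvalue equals 1 and the
#' basis spans the grid, \eqn{Q^{1/2}} acts as the identity and the
#' covariance reduces to \eqn{\varphi \star \tilde\varphi}.
#'
#' @param phi an \code{nf_smoothing}.
#' @param q an \code{nf_qspec}.
#' @param t time (>= 0), scales the covariance linearly.
#' @return Data frame as in [theoretical_covariance()].
#' @export
colored_covariance <- function(phi, q, t = 1) {
  grid <- q$grid
  v <- node_order(grid, smoothing_values(phi, grid))
  coef <- grid$cellvol * as.numeric(crossprod(q$basis, v))
  g <- as.numeric(q$basis %*% (sqrt(q$lambdas) * coef))
  # circular autocorrelation is origin-free, so node order works directly
  fa <- field_as_array(grid, g)
  ac <- Re(stats::fft(stats::fft(fa) * Conj(stats::fft(fa)),
                      inverse = TRUE)) / grid$n_nodes * grid$cellvol * t
  d <- grid$disp
  ord <- order(d)
  data.frame(displacement = d[ord], covariance = as.numeric(ac)[ord])
}
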