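#' @title Weight functions for the weighted-space formulation
#' @name weights
#' @description
#' The Hilbert-space formulation of the neural field equation with a
#' homogeneous (hence non-square-integrable) kernel lives in a weighted
#' space \eqn{L^2(\rho_w)} whose weight must satisfy the eigen-bound
#' condition C1':
#' \eqn{\int |w(x,y)| \rho(x) dx \le \Lambda_w \rho(y)}.  Two
#' constructions are provided: an explicit Fourier deconvolution for
#' homogeneous kernels, and a power iteration computing the spectral
#' radius and principal eigenfunction of the integral operator
#' \eqn{Jh(y) = \int |w(x,y)| h(x) dx} in the compact case.
NULL

#' Eigen-bound constant for a homogeneous kernel
#'
#' \eqn{\Lambda_w = \|w\|_{L^1} + 1}, the smallest convenient constant
#' strictly dominating the transform of \eqn{|w|} at every frequency.
#' The analytic norm is used when the kernel records one; otherwise the
#' norm is computed by quadrature of \eqn{|w|}.
#'
#' @param kernel a homogeneous \code{nf_kernel}.
#' @return \eqn{\Lambda_w > 1}.
#' @export
lambda_w <- function(kernel) {
  if (!kernel$homogeneous) {
    stop("the Fourier construction applies to homogeneous kernels only")
  }
  l1 <- kernel$analytic_l1
  if (is.na(l1)) {
    f <- function(d) abs(kernel$profile(d))
    l1 <- stats::integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
  }
  l1 + 1
}

#' Weight function by Fourier deconvolution
#'
#' For a homogeneous, continuous, integrable kernel, the weight
#' \deqn{\hat\rho(\xi) = \frac{\mathcal{F}z(\xi)}{\Lambda_w -
#'   \mathcal{F}v(\xi)}, \qquad v = |w|, \quad z(x) = e^{-|x|^2/2z_w^2},}
#' inverted on the grid, solves the residual identity
#' \eqn{\Lambda_w \rho(y) - (v \star \rho)(y) = z(y)} exactly in the
#' discrete world, which forces C1' with strict inequality since
#' \eqn{z > 0}.  The transform convention is
#' \eqn{\mathcal{F}v(\xi) = \int e^{-2\pi i x\xi} v(x) dx}.  By
#' construction the denominator is at least 1 at every frequency; a
#' smaller value indicates a quadrature artifact and raises an error.
#'
#' @param kernel a homogeneous \code{nf_kernel} with integrable profile.
#' @param grid an \code{nf_grid} with \code{N = 1}; the half-width
#'   should cover about 10 kernel length scales since the weight's tail
#'   decays only polynomially.
#' @param z_width width of the Gaussian source \eqn{z}; default 1.
#' @param tol slack allowed below the unit denominator bound before
#'   erroring.  The analytic bound is exactly 1, but on a grid the
#'   quadrature of \eqn{|w|} carries an \eqn{O(h^2)} error at the kinks
#'   that taking the absolute value introduces, so the discrete minimum
#'   can sit slightly below 1; the default slack absorbs that while
#'   still catching kernels the grid does not resolve (whose
#'   denominators drop far below 1 or go negative).
#' @return An object of class \code{nf_weight}: list with positive
#'   \code{values} on the grid, \code{Lambda}, \code{l1_norm},
#'   \code{grid}, \code{construction = "fourier"} and the source values
#'   \code{z}.
#' @export
rho_fourier <- function(kernel, grid, z_width = 1, tol = 1e-3) {
  stopifnot(grid$N == 1L)
  Lam <- lambda_w(kernel)
  v <- node_order(grid, abs(kernel_profile(kernel, grid)))
  z_nodes <- exp(-grid$axis^2 / (2 * z_width^2))
  vhat <- Re(grid_ft(grid, v))
  denom <- Lam - vhat
  if (min(denom) < 1 - tol) {
    stop(sprintf(paste("denominator bound violated: min(Lambda - Fv) =",
                       "%.3e < 1; the grid does not resolve the kernel"),
                 min(denom)))
  }
  rhohat <- grid_ft(grid, z_nodes) / denom
  rho <- grid_ift(grid, rhohat)
  structure(list(values = rho, Lambda = Lam,
                 l1_norm = grid_integral(grid, rho),
                 grid = grid, construction = "fourier",
                 z = z_nodes, z_width = z_width),
            class = "nf_weight")
}

# convert a field tabulated on displacement nodes (FFT order) to node
# order on the axis, and back (the maps are inverse to each other)
node_order <- function(grid, f_disp) {
  stopifnot(grid$N == 1L)
  f_disp[order(grid$disp)]
}

#' @export
print.nf_weight <- function(x, ...) {
  cat(sprintf("<nf_weight> %s construction, Lambda = %g, L1 norm = %g\n",
              x$construction, x$Lambda, x$l1_norm))
  invisible(x)
}

#' Verify the residual identity of the Fourier weight
#'
#' Recomputes \eqn{\Lambda \rho(y) - \int v(x - y)\rho(x) dx} by direct
#' (non-FFT) periodic quadrature and compares with the Gaussian source
#' \eqn{e^{-|y|^2/2 z_w^2}}; returns the maximal absolute error over the
#' grid.  A large error indicates a grid too coarse or too narrow for
#' the kernel; it is reported, not raised.
#'
#' @param rho an \code{nf_weight} built by [rho_fourier()].
#' @param kernel the kernel it was built from.
#' @param grid the grid it was built on (defaults to the weight's).
#' @return Maximal absolute residual error (numeric scalar).
#' @export
verify_residual <- function(rho, kernel, grid = rho$grid) {
  stopifnot(inherits(rho, "nf_weight"), grid$N == 1L)
  v <- abs(kernel_profile(kernel, grid))
  vfun_disp <- stats::approxfun(sort(grid$disp), v[order(grid$disp)])
  x <- grid$axis
  n <- grid$M
  conv <- numeric(n)
  for (j in seq_len(n)) {
    d <- x - x[j]
    d <- ((d + grid$L) %% (2 * grid$L)) - grid$L  # periodic displacement
    conv[j] <- sum(vfun_disp(d) * rho$values) * grid$h
  }
  target <- exp(-x^2 / (2 * rho$z_width^2))
  max(abs(rho$Lambda * rho$values - conv - target))
}

#' Truncated Neumann-series weight (reference construction)
#'
#' Computes \eqn{\rho = \Lambda^{-1} \sum_{k\ge 0} \Lambda^{-k}
#' v^{\star k} \star z} by repeated direct convolution until the tail
#' bound \eqn{\Lambda^{-k} \|v\|_1^k \|z\|_\infty} drops below
#' \code{tail_tol}.  Every term is nonnegative, which exhibits the
#' positivity of the Fourier weight; the series limit coincides with
#' [rho_fourier()] on the same grid and serves as its independent check.
#'
#' @inheritParams rho_fourier
#' @param tail_tol series truncation bound.
#' @return Numeric vector of weight values in node order.
#' @export
rho_neumann <- function(kernel, grid, z_width = 1, tail_tol = 1e-12) {
  stopifnot(grid$N == 1L)
  Lam <- lambda_w(kernel)
  v <- abs(kernel_profile(kernel, grid))
  z_disp <- exp(-grid$disp^2 / (2 * z_width^2))
  v1 <- grid_integral(grid, v)
  term <- z_disp  # v^{*0} * z
  acc <- term
  k <- 0
  repeat {
    k <- k + 1
    bound <- (v1 / Lam)^k * max(z_disp)
    term <- grid_conv(grid, v, term)
    acc <- acc + term / Lam^k
    if (bound < tail_tol || k > 200) break
  }
  node_order(grid, acc / Lam)
}

#' Principal eigenpair of the absolute-kernel integral operator
#'
#' Power iteration for the operator
#' \eqn{Jh(y) = \int |w(x, y)| h(x) dx} on the grid, normalized in the
#' norm \eqn{\|h\|_X = \max(\|h\|_{L^1}, \|h\|_{L^\infty})} under which
#' the operator is compact for kernels with uniformly small tails.  The
#' returned radius estimate approximates the spectral radius
#' \eqn{r(J)}; for kernels positive on a set of positive measure it is
#' bounded below by \eqn{\inf_{y\in\Omega} \int_\Omega |w(x,y)| dx} for
#' any box \eqn{\Omega}, and the eigenfunction is a valid C1' weight
#' with \eqn{\Lambda = r(J)}.
#'
#' @param kernel an \code{nf_kernel}.
#' @param grid an \code{nf_grid}.
#' @param max_iter iteration budget.
#' @param tol convergence tolerance on the residual
#'   \eqn{\|Jh - r h\|_X / r}.
#' @param start positive start vector; defaults to constant 1.
#' @return An object of class \code{nf_spectral}: list with
#'   \code{radius} (the estimate of \eqn{r(J)}), \code{eigenfunction}
#'   (normalized, \eqn{\|h\|_X = 1}), \code{iterations},
#'   \code{residuals} (trace of \eqn{\|Jh_k - r_k h_k\|_X}).
#' @export
power_iteration_weight <- function(kernel, grid, max_iter = 500,
                                   tol = 1e-12, start = NULL) {
  W <- kernel_matrix(kernel, grid, absolute = TRUE)
  n <- grid$n_nodes
  h <- if (is.null(start)) rep(1, n) else start
  if (any(h <= 0)) stop("the start vector must be positive")
  xnorm <- function(f) max(grid$cellvol * sum(abs(f)), max(abs(f)))
  h <- h / xnorm(h)
  res_trace <- numeric(0)
  r <- 0
  apply_J <- function(f) grid$cellvol * as.numeric(crossprod(W, f))
  for (k in seq_len(max_iter)) {
    Jh <- apply_J(h)
    r_new <- xnorm(Jh)
    if (r_new == 0) {
      return(structure(list(radius = 0, eigenfunction = h,
                            iterations = k, residuals = res_trace),
                       class = "nf_spectral"))
    }
    h_new <- Jh / r_new
    res <- xnorm(apply_J(h_new) - r_new * h_new)
    res_trace <- c(res_trace, res)
    conv <- res / r_new < tol
    h <- h_new; r <- r_new
    if (conv) {
      return(structure(list(radius = r, eigenfunction = h,
                            iterations = k, residuals = res_trace),
                       class = "nf_spectral"))
    }
  }
  stop(sprintf(paste("power iteration did not converge in %d iterations;",
                     "last residuals: %s"),
               max_iter,
               paste(signif(utils::tail(res_trace, 3), 3), collapse = ", ")))
}

#' @export
print.nf_spectral <- function(x, ...) {
  cat(sprintf("<nf_spectral> r(J) = %g after %d iterations (residual %g)\n",
              x$radius, x$iterations,
              if (length(x$residuals)) utils::tail(x$residuals, 1) else NA))
  invisible(x)
}

#' Lower bound on the spectral radius from a probe box
#'
#' \eqn{r(J) \ge m = \inf_{y \in \Omega} \int_\Omega |w(x, y)| dx} for
#' any bounded box \eqn{\Omega} of positive measure, evaluated by grid
#' quadrature over \code{omega = c(lo, hi)}.
#'
#' @param kernel an \code{nf_kernel}.
#' @param grid an \code{nf_grid} with \code{N = 1}.
#' @param omega numeric 2-vector, the probe interval.
#' @return The bound \eqn{m \ge 0}.
#' @export
spectral_radius_lower_bound <- function(kernel, grid, omega) {
  stopifnot(grid$N == 1L, length(omega) == 2, omega[1] < omega[2])
  x <- grid$axis[grid$axis >= omega[1] & grid$axis <= omega[2]]
  W <- outer(x, x, function(a, b) abs(kernel$evaluate(a, b)))
  min(colSums(W) * grid$h)
}

#' Constant weight for uniformly integrable kernels
#'
#' When \eqn{\sup_y \|w(\cdot, y)\|_{L^1} \le C}, the constant weight
#' \eqn{\rho \equiv 1} with \eqn{\Lambda = C} satisfies C1' on any
#' truncated grid.
#'
#' @param grid an \code{nf_grid}.
#' @param Lambda the constant \eqn{\Lambda > 0}.
#' @return An \code{nf_weight} with \code{construction = "constant"}.
#' @export
constant_weight <- function(grid, Lambda) {
  if (Lambda <= 0) stop("Lambda must be positive")
  structure(list(values = rep(1, grid$n_nodes), Lambda = Lambda,
                 l1_norm = grid$cellvol * grid$n_nodes, grid = grid,
                 construction = "constant", z = NULL, z_width = NA_real_),
            class = "nf_weight")
}
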