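#' @title Monte Carlo diagnostics: isometry, covariance, regularity
#' @name diagnostics
#' @description
#' Statistical verification of the structural properties of the
#' simulated noise and solution fields: the second-moment (Ito)
#' isometry of the discrete Walsh integral, the stationary spatial
#' covariance \eqn{t \varphi \star \tilde\varphi} of the smoothed
#' noise, and Hölder-regularity exponents in time (1/2, Brownian
#' scaling) and space (the shift-modulus exponent of \eqn{\varphi}),
#' estimated by second-order structure functions with log-log
#' regression.
NULL

#' Ito isometry of the discrete Walsh integral
#'
#' Draws replicates of the discrete Walsh integral
#' \eqn{I = \sum_{n,j} f(t_n, x_j) \Delta W_{n,j}} of a deterministic
#' square-summable integrand and returns the ratio of the sample second
#' moment of \eqn{I} to the exact discrete norm
#' \eqn{\sum f^2 \Delta t\, h^N}.  The population value of the ratio is
#' 1 (the Burkholder constant at \eqn{p = 2}); the Monte Carlo standard
#' error of the ratio is reported.
#'
#' @param f function of \code{(t, x)} (vectorized in \code{x}), or a
#'   matrix of integrand values (\code{n_steps x n_nodes}).
#' @param grid an \code{nf_grid} with \code{N = 1}.
#' @param T time horizon; \code{n_steps} uniform steps.
#' @param n_steps number of time steps.
#' @param replicates Monte Carlo sample size.
#' @param block replicates are generated in blocks of this size to
#'   bound memory.
#' @return List with \code{ratio}, \code{se} (standard error of the
#'   ratio), \code{norm2} (the discrete squared norm), and
#'   \code{replicates}.  Zero integrands give \code{ratio = NA} with a
#'   degenerate flag.
#' @export
ito_isometry_check <- function(f, grid, T = 1, n_steps = 100,
                               replicates = 10000, block = 500) {
  stopifnot(grid$N == 1L)
  dt <- T / n_steps
  fm <- if (is.function(f)) {
    t(vapply(seq_len(n_steps), function(n) f((n - 1) * dt, grid$axis),
             numeric(grid$M)))
  } else f
  stopifnot(nrow(fm) == n_steps, ncol(fm) == grid$M)
  norm2 <- sum(fm^2) * dt * grid$h
  if (norm2 == 0) {
    return(list(ratio = NA_real_, se = NA_real_, norm2 = 0,
                replicates = replicates, degenerate = TRUE))
  }
  sd1 <- sqrt(dt * grid$h)
  sq <- numeric(0)
  done <- 0
  while (done < replicates) {
    b <- min(block, replicates - done)
    acc <- numeric(b)
    for (n in seq_len(n_steps)) {
      Z <- matrix(stats::rnorm(grid$M * b, sd = sd1), grid$M, b)
      acc <- acc + as.numeric(crossprod(Z, fm[n, ]))
    }
    sq <- c(sq, acc^2)
    done <- done + b
  }
  ratio <- mean(sq) / norm2
  se <- stats::sd(sq) / (norm2 * sqrt(replicates))
  list(ratio = ratio, se = se, norm2 = norm2, replicates = replicates,
       degenerate = FALSE)
}

#' Simulate replicate paths of the smoothed noise field
#'
#' Cumulative sums of smoothed white-noise increments:
#' \eqn{W^\varphi(t_n, \cdot)} on a uniform time grid, one slice per
#' replicate.
#'
#' @param phi an \code{nf_smoothing}.
#' @param grid an \code{nf_grid} with \code{N = 1}.
#' @param T horizon; \code{n_steps} steps.
#' @param n_steps number of steps.
#' @param replicates number of independent paths.
#' @return Array \code{(n_steps + 1) x n_nodes x replicates} (time 0
#'   is the zero field).
#' @export
smoothed_noise_paths <- function(phi, grid, T = 1, n_steps = 64,
                                 replicates = 500) {
  stopifnot(grid$N == 1L)
  dt <- T / n_steps
  out <- array(0, c(n_steps + 1, grid$M, replicates))
  W <- matrix(0, grid$M, replicates)
  for (n in seq_len(n_steps)) {
    dW <- white_noise_increments(grid, dt, n = replicates)
    W <- W + smoothed_increment(dW, phi, grid)
    out[n + 1, , ] <- W
  }
  out
}

# structure-function slope: log RMS increment vs log lag.  The point
# estimate pools all replicates before taking logs (so the concave-log
# small-sample bias is divided by the replicate count and is
# negligible); the standard error comes from recomputing the pooled
# slope on replicate blocks, which respects the cross-lag correlation
# of the shared replicates.
structure_function_fit <- function(lag_values, msq_by_rep, n_blocks = 20) {
  x <- log(lag_values)
  X <- cbind(1, x)
  cw <- solve(crossprod(X), t(X))    # OLS coefficient weights
  pooled_slope <- function(rows) {
    m <- colMeans(msq_by_rep[rows, , drop = FALSE])
    sum(cw[2, ] * log(m)) / 2
  }
  R <- nrow(msq_by_rep)
  slope <- pooled_slope(seq_len(R))
  B <- max(2, min(n_blocks, floor(R / 10)))
  blk <- cut(seq_len(R), B, labels = FALSE)
  bs <- vapply(seq_len(B), function(b) pooled_slope(which(blk == b)),
               numeric(1))
  slope_se <- stats::sd(bs) / sqrt(B)
  list(slope = slope, se = slope_se, rms = sqrt(colMeans(msq_by_rep)))
}

#' Temporal Hölder exponent by structure functions
#'
#' Estimates the time-regularity exponent of a random field from the
#' scaling of its RMS time increment: for each dyadic lag
#' \eqn{\tau = k\,\Delta t}, computes the mean squared increment over
#' replicates, times and a node set, and regresses
#' \eqn{\log \mathrm{RMS}} on \eqn{\log \tau}.  For the smoothed noise
#' field the increment law is exactly
#' \eqn{E|\Delta W^\varphi|^2 = \|\varphi\|^2_{L^2}\tau}, so the
#' population slope is 1/2.
#'
#' @param paths array \code{(n_times) x n_nodes x replicates} on a
#'   uniform time grid.
#' @param dt time spacing of the array.
#' @param lags integer lags in steps; at least 4 spanning two dyadic
#'   octaves, and at least 2 steps each to stay above the
#'   discretization floor.
#' @return An object of class \code{nf_holder}: \code{exponent},
#'   \code{se}, \code{direction = "time"}, \code{lags}, \code{rms}.
#' @export
holder_exponent_time <- function(paths, dt, lags = c(2, 4, 8, 16)) {
  if (length(lags) < 4) stop("at least 4 lags are required")
  if (max(lags) / min(lags) < 4) stop("lags must span two dyadic octaves")
  nt <- dim(paths)[1]
  R <- dim(paths)[3]
  if (max(lags) >= nt) stop("largest lag exceeds the path length")
  msq <- sapply(lags, function(k) {
    d <- paths[(1 + k):nt, , , drop = FALSE] -
      paths[1:(nt - k), , , drop = FALSE]
    apply(d^2, 3, mean)  # per-replicate mean squared increment
  })
  if (all(msq == 0)) {
    return(structure(list(exponent = NA_real_, se = NA_real_,
                          direction = "time", lags = lags * dt,
                          rms = rep(0, length(lags)), degenerate = TRUE),
                     class = "nf_holder"))
  }
  fit <- structure_function_fit(lags * dt, msq)
  structure(list(exponent = fit$slope, se = fit$se, direction = "time",
                 lags = lags * dt, rms = fit$rms, replicates = R,
                 degenerate = FALSE),
            class = "nf_holder")
}

#' Spatial Hölder exponent by structure functions
#'
#' As [holder_exponent_time()] but for spatial increments
#' \eqn{Y(t, x + \ell) - Y(t, x)} at grid-commensurate displacements
#' \eqn{\ell = k h}.  For the smoothed noise the population law is
#' \eqn{E|W^\varphi(t,x) - W^\varphi(t,\tilde x)|^2 = t\,\|\varphi -
#' \tau_{\tilde x - x}\varphi\|^2_{L^2}}, so the slope estimates the
#' shift-modulus exponent of \eqn{\varphi} (1 for Gaussian, 1/2 for an
#' indicator).
#'
#' @param paths array \code{n_times x n_nodes x replicates}; spatial
#'   increments wrap periodically.
#' @param h grid spacing.
#' @param lags integer lags in cells; at least 4 spanning two octaves.
#' @param times indices of time slices to pool (default: the last).
#' @return An \code{nf_holder} with \code{direction = "space"}.
#' @export
holder_exponent_space <- function(paths, h, lags = c(1, 2, 4, 8),
                                  times = dim(paths)[1]) {
  if (length(lags) < 4) stop("at least 4 lags are required")
  if (max(lags) / min(lags) < 4) stop("lags must span two dyadic octaves")
  M <- dim(paths)[2]
  sl <- paths[times, , , drop = FALSE]
  msq <- sapply(lags, function(k) {
    idx <- (((0:(M - 1)) + k) %% M) + 1
    d <- sl[, idx, , drop = FALSE] - sl
    apply(d^2, 3, mean)
  })
  if (all(msq == 0)) {
    return(structure(list(exponent = NA_real_, se = NA_real_,
                          direction = "space", lags = lags * h,
                          rms = rep(0, length(lags)), degenerate = TRUE),
                     class = "nf_holder"))
  }
  fit <- structure_function_fit(lags * h, msq)
  structure(list(exponent = fit$slope, se = fit$se, direction = "space",
                 lags = lags * h, rms = fit$rms,
                 replicates = dim(paths)[3], degenerate = FALSE),
            class = "nf_holder")
}

#' @export
print.nf_holder <- function(x, ...) {
  cat(sprintf("<nf_holder> %s exponent %.4f (se %.4f), lags %s\n",
              x$direction, x$exponent, x$se,
              paste(signif(x$lags, 3), collapse = ", ")))
  invisible(x)
}

#' Analytic shift-modulus scaling exponent
#'
#' Computes the exact shift modulus of a smoothing kernel at dyadic
#' grid-commensurate shifts and the log-log regression slope, without
#' any Monte Carlo: the deterministic counterpart of
#' [holder_exponent_space()].  For an indicator kernel the modulus is
#' \eqn{\sqrt{2|z|}} exactly, so the slope is \eqn{1/2} to machine
#' precision.
#'
#' @param phi an \code{nf_smoothing}.
#' @param grid an \code{nf_grid} with \code{N = 1}.
#' @param shifts shifts (multiples of \code{h}); default 4 dyadic
#'   multiples starting at \code{4 h}.
#' @return List with \code{slope}, \code{shifts}, \code{moduli}.
#' @export
shift_modulus_exponent <- function(phi, grid,
                                   shifts = grid$h * c(4, 8, 16, 32)) {
  mods <- vapply(shifts, function(z) shift_modulus(phi, z, grid),
                 numeric(1))
  if (any(mods == 0)) stop("zero modulus; enlarge the shifts")
  fit <- stats::lm(log(mods) ~ log(shifts))
  list(slope = unname(stats::coef(fit)[2]), shifts = shifts,
       moduli = mods)
}

#' Empirical vs theoretical covariance of the smoothed noise
#'
#' Draws replicates of \eqn{W^\varphi(t, \cdot)} (a single exact
#' Gaussian increment of length \eqn{t}), computes the per-replicate
#' circular spatial autocovariance, and compares the replicate mean
#' with [theoretical_covariance()] at every displacement.  Errors are
#' judged against the replicate standard errors.
#'
#' @param phi an \code{nf_smoothing}.
#' @param t time.
#' @param grid an \code{nf_grid} with \code{N = 1}.
#' @param replicates at least 500.
#' @return List with \code{table} (displacement, empirical,
#'   theoretical, se) and \code{max_abs_error}, \code{max_error_in_se}
#'   (the maximum of |error|/se over displacements).
#' @export
covariance_comparison <- function(phi, t, grid, replicates = 2000) {
  stopifnot(grid$N == 1L)
  if (replicates < 500) stop("at least 500 replicates are required")
  dW <- white_noise_increments(grid, t, n = replicates)
  W <- smoothed_increment(dW, phi, grid)  # exact draw of W^phi(t, .)
  # per-replicate circular autocovariance via FFT
  Fh <- stats::mvfft(W)
  ac <- Re(stats::mvfft(Fh * Conj(Fh), inverse = TRUE)) / grid$M
  ac <- ac * grid$h / (2 * grid$L)  # spatial average of products
  emp <- rowMeans(ac)
  se <- apply(ac, 1, stats::sd) / sqrt(replicates)
  theo <- theoretical_covariance(phi, t, grid)
  ord <- order(grid$disp)
  tab <- data.frame(displacement = grid$disp[ord],
                    empirical = emp[ord],
                    theoretical = theo$covariance,
                    se = se[ord])
  err <- abs(tab$empirical - tab$theoretical)
  list(table = tab,
       max_abs_error = max(err),
       max_error_in_se = max(err / pmax(tab$se, .Machine$double.eps)))
}
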