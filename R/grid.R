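#' Truncated periodic spatial grid
#'
#' Constructs the lattice on which every field in the package lives: a
#' node-centered, periodic discretization of the half-open box
#' \eqn{[-L, L)^N} with \code{M} points per axis and spacing
#' \eqn{h = 2L/M}.  Periodicity makes circular FFT convolution the exact
#' discrete counterpart of convolution on the box, which all kernel and
#' noise operations rely on.
#'
#' @param N spatial dimension, 1 or 2.
#' @param L half-width of the box (space units).
#' @param M number of points per axis (at least 4).
#' @return An object of class \code{nf_grid} with components \code{N},
#'   \code{L}, \code{M}, spacing \code{h}, \code{axis} (node coordinates
#'   per axis), \code{disp} (displacement coordinates, wrapped to
#'   \eqn{[-L, L)}, with index 1 corresponding to zero displacement),
#'   \code{n_nodes} and cell volume \code{cellvol}.
#' @examples
#' g <- grid_spec(N = 1, L = 10, M = 256)
#' g$h * g$M == 2 * g$L
#' @export
grid_spec <- function(N = 1, L = 10, M = 256) {
  if (!N %in% c(1L, 2L)) stop("dimension N must be 1 or 2")
  if (L <= 0) stop("half-width L must be positive")
  M <- as.integer(M)
  if (M < 4) stop("at least 4 points per axis are required")
  if (M %% 2L != 0L) stop("M must be even (the grid pairs x with -x)")
  h <- 2 * L / M
  axis <- -L + h * (0:(M - 1))
  # displacement nodes in FFT order: 0, h, ..., L - h, -L, ..., -h
  disp <- ((h * (0:(M - 1)) + L) %% (2 * L)) - L
  structure(
    list(N = as.integer(N), L = L, M = M, h = h,
         axis = axis, disp = disp,
         n_nodes = M^N, cellvol = h^N),
    class = "nf_grid")
}

#' @export
print.nf_grid <- function(x, ...) {
  cat(sprintf("<nf_grid> [-%g, %g)^%d, M = %d per axis (h = %g), %d nodes\n",
              x$L, x$L, x$N, x$M, x$h, x$n_nodes))
  invisible(x)
}

#' Node coordinates of a grid
#'
#' @param grid an \code{nf_grid}.
#' @return For \code{N = 1} a numeric vector; for \code{N = 2} a matrix
#'   with one row per node (column-major over the second axis) and one
#'   column per coordinate.
#' @export
grid_nodes <- function(grid) {
  if (grid$N == 1L) return(grid$axis)
  as.matrix(expand.grid(x1 = grid$axis, x2 = grid$axis))
}

#' Displacement coordinates of a grid in FFT order
#'
#' Index 1 is the zero displacement; used to tabulate homogeneous kernel
#' profiles and smoothing kernels so that circular convolution aligns.
#'
#' @inheritParams grid_nodes
#' @return As \code{grid_nodes}, but for wrapped displacements.
#' @export
grid_displacements <- function(grid) {
  if (grid$N == 1L) return(grid$disp)
  as.matrix(expand.grid(x1 = grid$disp, x2 = grid$disp))
}

# reshape a flat field into the array the FFT expects
field_as_array <- function(grid, f) {
  if (grid$N == 1L) as.numeric(f) else matrix(f, grid$M, grid$M)
}

#' Cell-weighted integral of a grid field
#'
#' Riemann sum \eqn{h^N \sum_i f(x_i)} over the box.
#'
#' @param grid an \code{nf_grid}.
#' @param f field values on the grid nodes.
#' @export
grid_integral <- function(grid, f) grid$cellvol * sum(f)

#' Discrete L2 norm of a grid field
#'
#' @inheritParams grid_integral
#' @export
grid_l2_norm <- function(grid, f) sqrt(grid$cellvol * sum(f^2))

#' Circular convolution of two grid fields
#'
#' Computes the periodic convolution \eqn{(f * g)(x) = h^N \sum_y f(x-y) g(y)}
#' by FFT.  With \code{cellvol = FALSE} the plain weighted sum
#' \eqn{\sum_y f(x-y) g(y)} is returned, which is the form needed when
#' \code{g} already carries the cell measure (white-noise increments).
#'
#' @param grid an \code{nf_grid}.
#' @param f values of the convolving function on the displacement nodes
#'   (FFT order, see \code{grid_displacements}).
#' @param g field values on the grid nodes, or a matrix with one column
#'   per realization when \code{N = 1}.
#' @param cellvol multiply by the cell volume \eqn{h^N}? Default \code{TRUE}.
#' @return The convolved field, same shape as \code{g}.
#' @export
grid_conv <- function(grid, f, g, cellvol = TRUE) {
  scale <- if (cellvol) grid$cellvol else 1
  if (is.matrix(g) && grid$N == 1L && length(f) == nrow(g)) {
    # column-wise convolution of an ensemble
    fh <- stats::fft(f)
    out <- Re(stats::mvfft(stats::mvfft(g) * fh, inverse = TRUE)) / grid$M
    return(out * scale)
  }
  fa <- field_as_array(grid, f)
  ga <- field_as_array(grid, g)
  out <- Re(stats::fft(stats::fft(fa) * stats::fft(ga), inverse = TRUE)) /
    grid$n_nodes
  if (grid$N == 2L) out <- as.numeric(out)
  out * scale
}

#' Discrete Fourier transform with the analysts' convention
#'
#' Approximates \eqn{\hat f(\xi) = \int e^{-2\pi i x\xi} f(x) dx} on the
#' grid's natural frequencies \eqn{\xi_k = k/(2L)},
#' \eqn{k = 0, 1, \dots, M-1} (wrapped to negative frequencies past
#' \eqn{M/2}), by the rectangle rule.  One-dimensional grids only; the
#' phase factor \eqn{(-1)^k} accounts for the grid starting at \eqn{-L}.
#'
#' @param grid an \code{nf_grid} with \code{N = 1}.
#' @param f field values on the grid nodes.
#' @return Complex vector of transform values at the grid frequencies.
#' @seealso [grid_freqs()], [grid_ift()]
#' @export
grid_ft <- function(grid, f) {
  stopifnot(grid$N == 1L)
  k <- 0:(grid$M - 1)
  grid$h * (-1)^k * stats::fft(f)
}

#' Inverse of [grid_ft()]
#'
#' @param grid an \code{nf_grid} with \code{N = 1}.
#' @param fhat complex values on the grid frequencies.
#' @return Real field values on the grid nodes (imaginary parts, which are
#'   at roundoff level for transforms of real even data, are dropped).
#' @export
grid_ift <- function(grid, fhat) {
  stopifnot(grid$N == 1L)
  k <- 0:(grid$M - 1)
  dxi <- 1 / (2 * grid$L)
  Re(stats::fft((-1)^k * fhat, inverse = TRUE)) * dxi
}

#' Natural frequencies of a one-dimensional grid
#'
#' @param grid an \code{nf_grid} with \code{N = 1}.
#' @return Frequencies \eqn{\xi_k = k/(2L)} in FFT order (negative
#'   frequencies wrapped), matching [grid_ft()].
#' @export
grid_freqs <- function(grid) {
  stopifnot(grid$N == 1L)
  k <- 0:(grid$M - 1)
  k[k >= grid$M / 2] <- k[k >= grid$M / 2] - grid$M
  k / (2 * grid$L)
}
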