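#' Rectified-quadratic transfer function
#'
#' The input-output transfer function of each unit, `phi(u) = max(u, 0)^2`,
#' applied elementwise, and its derivative `phi'(u) = 2 * max(u, 0)` (the
#' one-sided derivative at 0 is 0; left and right limits agree).
#'
#' @param u Input current (scalar, vector or matrix); must be finite.
#' @return Rates (or gains) with the shape of `u`.
#' @examples
#' transfer(c(-1, 0, 3))       # 0 0 9
#' transfer_deriv(c(-2, 0, 3)) # 0 0 6
#' @export
transfer <- function(u) {
  if (!all(is.finite(u))) stop("non-finite input current", call. = FALSE)
  pmax(u, 0)^2
}

#' @rdname transfer
#' @export
transfer_deriv <- function(u) {
  if (!all(is.finite(u))) stop("non-finite input current", call. = FALSE)
  2 * pmax(u, 0)
}

#' Fourier coefficient of the wrapped-Gaussian coupling
#'
#' The periodic Gaussian coupling kernel on the unit torus is defined by its
#' Fourier coefficients `exp(-2 * ||n||^2 * pi^2 * sigma^2)` at integer mode
#' `n`. The coefficient depends only on the wave number `k = ||n||`.
#'
#' @param n Integer mode vector (length `dim`) or a scalar wave number.
#' @param sigma Projection width (> 0).
#' @return The Fourier coefficient, in `(0, 1]`.
#' @export
gaussian_mode_coef <- function(n, sigma) {
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  exp(-2 * sum(n^2) * pi^2 * sigma^2)
}

#' Spectral representation of the periodic Gaussian coupling
#'
#' Builds the per-mode Fourier coefficients of the wrapped-Gaussian kernel of
#' width `sigma` on the grid's integer mode lattice (up to the Nyquist mode),
#' the equivalent real-space 1D kernel, and the symmetric circulant matrix
#' used by the integrator. Because the kernel's coefficients factorize across
#' axes, the 2D spectral convolution equals `G %*% F %*% G`.
#'
#' @param n_side Units per axis.
#' @param sigma Projection width (fraction of domain length), > 0.
#' @param dim Spatial dimension (1 or 2).
#' @return An object of class `spectral_kernel` with fields `modes` (per-axis
#'   integer mode numbers on the FFT lattice), `axis_coef` (per-axis
#'   coefficients), `coef` (full per-mode coefficient vector/matrix),
#'   `kernel` (real-space 1D kernel weights, summing to 1) and `G` (the
#'   circulant matrix).
#' @export
spectral_kernel <- function(n_side, sigma, dim = 2) {
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  n <- as.integer(n_side)
  i <- 0:(n - 1)
  modes <- ifelse(i <= n / 2, i, i - n)
  axis_coef <- exp(-2 * modes^2 * pi^2 * sigma^2)
  coef <- if (dim == 2) outer(axis_coef, axis_coef) else axis_coef
  kernel <- Re(fft(axis_coef, inverse = TRUE)) / n
  G <- matrix(0, n, n)
  for (j in seq_len(n)) G[, j] <- kernel[((i - (j - 1)) %% n) + 1]
  structure(list(n_side = n, dim = as.integer(dim), sigma = sigma,
                 modes = modes, axis_coef = axis_coef, coef = coef,
                 kernel = kernel, G = G),
            class = "spectral_kernel")
}

#' @export
print.spectral_kernel <- function(x, ...) {
  cat(sprintf(
    "Wrapped-Gaussian spectral kernel: sigma=%g, %dD, n_side=%d\n",
    x$sigma, x$dim, x$n_side))
  cat(sprintf("  g~(0)=%g, g~(1)=%g, g~(Nyquist)=%.3g\n",
              x$axis_coef[1], x$axis_coef[2], min(x$axis_coef)))
  invisible(x)
}

#' Periodic convolution with the Gaussian coupling kernel
#'
#' Convolves a rate field with the wrapped-Gaussian kernel by forward FFT,
#' per-mode multiplication with the kernel coefficients, and inverse FFT.
#' Since the coefficient at mode 0 is 1, a spatially constant field maps to
#' itself.
#'
#' @param field Rate field: a vector (1D) or `n_side x n_side` matrix (2D).
#' @param kernel A [spectral_kernel()] matching the field's grid.
#' @return The convolved field, same shape as `field`.
#' @export
apply_coupling <- function(field, kernel) {
  stopifnot(inherits(kernel, "spectral_kernel"))
  if (kernel$dim == 2) {
    if (!is.matrix(field) || any(dim(field) != kernel$n_side))
      stop("field shape does not match kernel grid", call. = FALSE)
    Re(fft(fft(field) * kernel$coef, inverse = TRUE)) / length(field)
  } else {
    if (is.matrix(field) || length(field) != kernel$n_side)
      stop("field shape does not match kernel grid", call. = FALSE)
    Re(fft(fft(field) * kernel$coef, inverse = TRUE)) / length(field)
  }
}
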