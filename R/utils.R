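# Small numerical helpers shared across modules.

# Conversion between a Gaussian sigma and its full width at half maximum.
FWHM_FACTOR <- 2 * sqrt(2 * log(2))

#' Full width at half maximum of a Gaussian
#'
#' @param sigma Gaussian standard deviation (any unit).
#' @return FWHM in the same unit, `2 * sqrt(2 * log(2)) * sigma`.
#' @export
gaussian_fwhm <- function(sigma) FWHM_FACTOR * sigma

# Wrapped (circulant) 1D Gaussian kernel of length n, normalized to sum 1.
gauss_kernel_wrapped <- function(n, sigma_px) {
  i <- 0:(n - 1)
  d <- pmin(i, n - i)
  k <- exp(-d^2 / (2 * sigma_px^2))
  k / sum(k)
}

# Circular FFT Gaussian blur; conserves total intensity exactly.
fft_gaussian_blur <- function(mat, sigma_px) {
  if (sigma_px <= 0) return(mat)
  ny <- nrow(mat)
  nx <- ncol(mat)
  kern <- outer(gauss_kernel_wrapped(ny, sigma_px), gauss_kernel_wrapped(nx, sigma_px))
  Re(fft(fft(mat) * fft(kern), inverse = TRUE)) / (ny * nx)
}

# Circular FFT convolution with an arbitrary wrapped kernel.
fft_convolve <- function(mat, kern) {
  Re(fft(fft(mat) * fft(kern), inverse = TRUE)) / (nrow(mat) * ncol(mat))
}

# Bilinear interpolation of matrix `mat` (rows = y, cols = x, 0-based pixel
# coordinates) at points (xp, yp) in pixel units. Points outside the grid
# return NA.
bilinear_sample <- function(mat, xp, yp) {
  nx <- ncol(mat)
  ny <- nrow(mat)
  out <- rep(NA_real_, length(xp))
  ok <- xp >= 0 & xp <= nx - 1 & yp >= 0 & yp <= ny - 1
  if (any(ok)) {
    out[ok] <- pracma::interp2(x = 0:(nx - 1), y = 0:(ny - 1), Z = mat,
                               xp = xp[ok], yp = yp[ok], method = "linear")
  }
  out
}

# Shift an image by (dx, dy) pixels with bilinear interpolation (used by
# tests and the flow-series oracle; out-of-frame samples become 0).
translate_bilinear <- function(mat, dx, dy) {
  nx <- ncol(mat)
  ny <- nrow(mat)
  g <- expand.grid(x = 0:(nx - 1), y = 0:(ny - 1))
  v <- bilinear_sample(mat, g$x - dx, g$y - dy)
  v[is.na(v)] <- 0
  matrix(v, nrow = ny, ncol = nx, byrow = TRUE)
}

# Draw from a zero-mean Gaussian random field with squared-exponential
# covariance exp(-d^2 / (2 l^2)) evaluated at the given points (n x 2 matrix,
# um). Returns an n x n_fields matrix of independent field draws.
grf_at_points <- function(pts, length_scale, n_fields = 1) {
  n <- nrow(pts)
  K <- exp(-as.matrix(dist(pts))^2 / (2 * length_scale^2))
  L <- chol(K + diag(1e-8, n))
  crossprod(L, matrix(rnorm(n * n_fields), n, n_fields))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
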