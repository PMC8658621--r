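# Separable Gaussian smoothing with truncated, edge-renormalised kernels.
#
# The convolution is expressed as banded matrix products so that each row of
# the operator sums to exactly 1 even where the kernel is truncated at the
# image border. That makes smoothing of a constant field return the constant
# exactly, so the Gaussian-subtraction high-pass of a constant slice is
# identically zero (no DC leakage at edges).

gaussian_kernel_1d <- function(sigma_px) {
  if (sigma_px <= 1e-8) return(1)
  r <- max(1L, as.integer(ceiling(4 * sigma_px)))
  x <- (-r):r
  k <- exp(-0.5 * (x / sigma_px)^2)
  k / sum(k)
}

# n x n convolution operator for a symmetric kernel, rows renormalised to 1.
conv_matrix_1d <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (off in -r:r) {
    idx <- seq_len(n)
    j <- idx + off
    ok <- j >= 1L & j <= n
    K[cbind(idx[ok], j[ok])] <- kernel[off + r + 1L]
  }
  K / rowSums(K)
}

# Gaussian-smooth a 2-D matrix; sigma in pixels per axis (rows, cols).
smooth_slice <- function(x, sigma_px) {
  n <- dim(x)
  if (sigma_px[1] > 1e-8) x <- conv_matrix_1d(n[1], gaussian_kernel_1d(sigma_px[1])) %*% x
  if (sigma_px[2] > 1e-8) x <- x %*% t(conv_matrix_1d(n[2], gaussian_kernel_1d(sigma_px[2])))
  x
}

# Gaussian-smooth a 3-D array; sigma in voxels per axis.
smooth_field3 <- function(arr, sigma_vox) {
  d <- dim(arr)
  if (sigma_vox[1] > 1e-8 || sigma_vox[2] > 1e-8) {
    K1 <- if (sigma_vox[1] > 1e-8) conv_matrix_1d(d[1], gaussian_kernel_1d(sigma_vox[1])) else NULL
    K2 <- if (sigma_vox[2] > 1e-8) t(conv_matrix_1d(d[2], gaussian_kernel_1d(sigma_vox[2]))) else NULL
    for (k in seq_len(d[3])) {
      sl <- arr[, , k]
      if (!is.null(K1)) sl <- K1 %*% sl
      if (!is.null(K2)) sl <- sl %*% K2
      arr[, , k] <- sl
    }
  }
  if (sigma_vox[3] > 1e-8 && d[3] > 1L) {
    K3 <- conv_matrix_1d(d[3], gaussian_kernel_1d(sigma_vox[3]))
    m <- matrix(arr, d[1] * d[2], d[3]) %*% t(K3)
    arr <- array(m, d)
  }
  arr
}
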