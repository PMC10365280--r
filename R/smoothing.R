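# Separable Gaussian smoothing of 3D arrays, implemented as one banded
# kernel-matrix multiply per axis (BLAS-bound, no loops over voxels).
# Kernels are truncated at 3 sigma and renormalised row-wise, so the
# operation preserves constants exactly, including at the boundary.

gauss_kernel_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  hw <- max(1L, as.integer(ceiling(3 * sigma_vox)))
  idx <- seq_len(n)
  K <- matrix(0, n, n)
  for (o in -hw:hw) {
    w <- exp(-o^2 / (2 * sigma_vox^2))
    rows <- idx[idx + o >= 1 & idx + o <= n]
    K[cbind(rows, rows + o)] <- w
  }
  K / rowSums(K)
}

#' Gaussian-smooth a 3D array
#'
#' @param arr 3D numeric array.
#' @param sigma_mm smoothing sigma in mm (scalar or per-axis triple).
#' @param spacing voxel spacing in mm (triple).
#' @return smoothed array of the same dimensions.
#' @keywords internal
smooth3d <- function(arr, sigma_mm, spacing = c(1, 1, 1)) {
  d <- dim(arr)
  sig <- rep_len(sigma_mm, 3) / spacing
  if (all(sig <= 0)) return(arr)
  if (sig[1] > 0) {
    K <- gauss_kernel_matrix(d[1], sig[1])
    arr <- array(K %*% matrix(arr, d[1]), d)
  }
  if (sig[2] > 0) {
    K <- gauss_kernel_matrix(d[2], sig[2])
    ap <- aperm(arr, c(2, 1, 3))
    ap <- array(K %*% matrix(ap, d[2]), c(d[2], d[1], d[3]))
    arr <- aperm(ap, c(2, 1, 3))
  }
  if (sig[3] > 0) {
    K <- gauss_kernel_matrix(d[3], sig[3])
    arr <- array(matrix(arr, d[1] * d[2]) %*% t(K), d)
  }
  arr
}

# smoothed unit-RMS Gaussian random field on a grid
random_smooth_field <- function(d, spacing, sigma_mm) {
  f <- smooth3d(array(stats::rnorm(prod(d)), d), sigma_mm, spacing)
  rms <- sqrt(mean(f^2))
  if (rms < .Machine$double.eps) return(f)
  f / rms
}
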