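#' Separable Gaussian spatial smoothing
#'
#' Smooths a 3D volume (or each volume of a 4D run) with a separable Gaussian
#' kernel of the given full-width-at-half-maximum. Per-axis kernel standard
#' deviation is `(fwhm / voxel_size) / (2 * sqrt(2 * log(2)))` voxels. Edges
#' use renormalized (unit-row-sum) convolution, so constant volumes pass
#' through unchanged and the mass of any interior impulse is conserved.
#' `fwhm = 0` is the identity.
#'
#' @param volume A 3D `(x, y, z)` or 4D `(x, y, z, t)` array.
#' @param fwhm Full width at half maximum, mm.
#' @param voxel_size Voxel edge length(s), mm; scalar or length 3.
#' @return An array of the same shape.
#' @export
gaussian_smooth <- function(volume, fwhm, voxel_size = 1) {
  if (length(fwhm) != 1 || !is.finite(fwhm) || fwhm < 0) {
    stop_invalid("`fwhm` must be a single non-negative number.")
  }
  nd <- length(dim(volume))
  if (!nd %in% c(3, 4)) stop_invalid("`volume` must be a 3D or 4D array.")
  if (fwhm == 0) return(volume)
  voxel_size <- rep_len(voxel_size, 3)
  sigma <- (fwhm / voxel_size) / (2 * sqrt(2 * log(2)))
  for (axis in 1:3) {
    volume <- convolve_axis(volume, axis, gaussian_band(dim(volume)[axis], sigma[axis]))
  }
  volume
}

# Band matrix implementing normalized 1D Gaussian convolution (rows sum to 1).
gaussian_band <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  radius <- ceiling(4 * sigma)
  offsets <- -radius:radius
  kern <- exp(-offsets^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  band <- matrix(0, n, n)
  for (j in seq_along(offsets)) {
    idx <- seq_len(n) + offsets[j]
    ok <- idx >= 1 & idx <= n
    band[cbind(which(ok), idx[ok])] <- band[cbind(which(ok), idx[ok])] + kern[j]
  }
  band / rowSums(band)
}

# Apply a band matrix along one axis of an n-dimensional array.
convolve_axis <- function(arr, axis, band) {
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_along(d), axis))
  a <- aperm(arr, perm)
  m <- band %*% matrix(a, d[axis], prod(d[-axis]))
  a <- array(m, dim = d[perm])
  aperm(a, order(perm))
}

#' Discrete-cosine high-pass filter
#'
#' Regresses a discrete cosine drift basis (all DCT regressors with frequency
#' at or below `cutoff_hz`) out of each series. The basis is orthogonal to the
#' constant, so the series mean is preserved, the filter is an exact linear
#' projection, and applying it twice equals applying it once.
#'
#' @param series A numeric vector or a `t x n` matrix (columns filtered
#'   independently).
#' @param cutoff_hz Cutoff frequency in Hz (drift below this is removed).
#' @param tr Sampling interval in seconds.
#' @return Filtered data of the same shape.
#' @export
highpass_filter <- function(series, cutoff_hz = 0.01, tr) {
  x <- if (is.matrix(series)) series else matrix(series, ncol = 1)
  n <- nrow(x)
  if (n < 8) stop_invalid("High-pass filtering needs at least 8 time points.")
  if (tr <= 0) stop_invalid("`tr` must be positive.")
  nyquist <- 1 / (2 * tr)
  if (cutoff_hz <= 0 || cutoff_hz >= nyquist) {
    stop_invalid("`cutoff_hz` must lie in (0, Nyquist = %.4f Hz).", nyquist)
  }
  basis <- dct_basis(n, tr, cutoff_hz)
  out <- if (is.null(basis)) x else x - basis %*% crossprod(basis, x)
  if (is.matrix(series)) out else drop(out)
}

# Orthonormal DCT-II drift regressors with frequency <= cutoff (constant
# excluded); NULL when the cutoff admits none.
dct_basis <- function(n, tr, cutoff_hz) {
  k_max <- floor(2 * n * tr * cutoff_hz)
  if (k_max < 1) return(NULL)
  i <- seq_len(n)
  basis <- vapply(seq_len(k_max), function(k) {
    cos(pi * (2 * i - 1) * k / (2 * n))
  }, numeric(n))
  sweep(basis, 2, sqrt(colSums(basis^2)), "/")
}

#' Preprocess all runs of a dataset
#'
#' Applies, per run, spatial Gaussian smoothing followed by discrete-cosine
#' high-pass filtering of every voxel time series. The temporal mean of each
#' voxel is preserved by the filter, so percent-signal-change scaling remains
#' well defined downstream.
#'
#' @param dataset A `bold_dataset`.
#' @param fwhm Smoothing FWHM in mm (0 disables smoothing).
#' @param voxel_size Voxel edge length(s) in mm.
#' @param cutoff_hz High-pass cutoff in Hz (`NULL` disables filtering).
#' @return The dataset with preprocessed run matrices.
#' @export
preprocess_dataset <- function(dataset, fwhm = 7, voxel_size = 3,
                               cutoff_hz = 0.01) {
  vol_dim <- dataset$vol_dim
  for (s in seq_along(dataset$runs)) {
    for (cond in dataset$conditions) {
      m <- dataset$runs[[s]][[cond]]
      if (fwhm > 0) {
        arr <- array(t(m), c(vol_dim, nrow(m)))
        arr <- gaussian_smooth(arr, fwhm, voxel_size)
        m <- t(matrix(arr, prod(vol_dim), nrow(m)))
      }
      if (!is.null(cutoff_hz)) {
        m <- highpass_filter(m, cutoff_hz = cutoff_hz, tr = dataset$tr)
      }
      dataset$runs[[s]][[cond]] <- m
    }
  }
  dataset$preprocessing <- list(fwhm = fwhm, voxel_size = voxel_size,
                                cutoff_hz = cutoff_hz)
  dataset
}
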