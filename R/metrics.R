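#' Mean squared error between two volumes
#'
#' @param a,b `volume3d` objects or arrays of identical dimensions.
#' @return Mean of squared voxel differences; 0 iff identical.
#' @export
mse <- function(a, b) {
  check_same_dims(a, b)
  mean((vol_data(a) - vol_data(b))^2)
}

#' Root mean squared error
#'
#' @inheritParams mse
#' @return `sqrt(mse(a, b))`.
#' @export
rmse <- function(a, b) sqrt(mse(a, b))

#' Peak signal-to-noise ratio in dB
#'
#' `10 * log10(data_range^2 / MSE)`. Volumes are normalized to \[0, 1\]
#' throughout the pipeline, so the data range defaults to 1. Identical
#' inputs yield the `Inf` sentinel, which aggregation excludes from means.
#'
#' @inheritParams mse
#' @param data_range Peak-to-peak intensity range (> 0).
#' @return PSNR in dB (`Inf` for identical inputs).
#' @export
psnr <- function(a, b, data_range = 1) {
  stopifnot(data_range > 0)
  m <- mse(a, b)
  if (m == 0) return(Inf)
  10 * log10(data_range^2 / m)
}

# Normalized 1D Gaussian window.
gaussian_kernel1d <- function(size = 7L, sigma = 1.5) {
  half <- (size - 1) / 2
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable valid-mode filtering of a 3D array with the same 1D kernel on
# each axis, via per-axis band-matrix products.
filter_valid3d <- function(arr, k1d) {
  ksz <- length(k1d)
  for (axis in 1:3) {
    d <- dim(arr)
    n_out <- d[1] - ksz + 1L
    band <- matrix(0, n_out, d[1])
    for (j in seq_len(ksz)) band[cbind(seq_len(n_out), seq_len(n_out) + j - 1L)] <- k1d[j]
    m <- band %*% matrix(arr, d[1], d[2] * d[3])
    arr <- aperm(array(m, c(n_out, d[2], d[3])), c(2, 3, 1))
  }
  arr  # three cyclic permutations restore the original axis order
}

#' Structural similarity index for 3D volumes
#'
#' Mean local SSIM over a sliding 3D Gaussian-weighted window (default
#' 7x7x7, sigma 1.5) with the standard stabilizing constants
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`. Local statistics are weighted
#' moments (no sample-size correction) and only positions where the full
#' window fits are used. Equals 1 iff the volumes are identical.
#'
#' @inheritParams psnr
#' @param window Odd window size; every volume dimension must be >= it.
#' @param sigma Gaussian window width.
#' @return A scalar in \[-1, 1\].
#' @export
ssim3d <- function(a, b, data_range = 1, window = 7L, sigma = 1.5) {
  check_same_dims(a, b)
  x <- vol_data(a); y <- vol_data(b)
  if (any(dim(x) < window))
    stop(fdosr_error("volume smaller than the SSIM window", "fdosr_shape_error"))
  k <- gaussian_kernel1d(window, sigma)
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  mu_x <- filter_valid3d(x, k)
  mu_y <- filter_valid3d(y, k)
  sxx <- filter_valid3d(x * x, k) - mu_x^2
  syy <- filter_valid3d(y * y, k) - mu_y^2
  sxy <- filter_valid3d(x * y, k) - mu_x * mu_y
  num <- (2 * mu_x * mu_y + c1) * (2 * sxy + c2)
  den <- (mu_x^2 + mu_y^2 + c1) * (sxx + syy + c2)
  mean(num / den)
}
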