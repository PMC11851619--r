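#' 3D Fourier transform of a volume
#'
#' Computes the spectrum of a real-valued reconstructed image — the
#' "synthetic" frequency domain, as distinct from raw scanner k-space. The
#' transform is orthonormally scaled (divided by `sqrt(N)`), so total
#' spectral energy equals total image energy (Parseval) and loss magnitudes
#' are stable across grid sizes. The returned spectrum is unshifted
#' (`dc_at_corner`): the DC coefficient sits at index \[1, 1, 1\] and the
#' highest spatial frequencies sit near the array center.
#'
#' @param vol A `volume3d` or 3D array with finite values.
#' @return An object of class `kspace3d` with complex `data` and a
#'   `convention` field (`"dc_at_corner"` or `"dc_centered"`).
#' @export
fft3d <- function(vol) {
  x <- vol_data(vol)
  if (!all(is.finite(x)))
    stop(fdosr_error("cannot transform non-finite volume", "fdosr_nonfinite_error"))
  structure(list(data = stats::fft(x) / sqrt(length(x)),
                 convention = "dc_at_corner"),
            class = "kspace3d")
}

#' Inverse 3D Fourier transform
#'
#' @param ks A `kspace3d`.
#' @param spacing Spacing for the reconstructed volume.
#' @return A `volume3d`; the (numerically negligible) imaginary residue of
#'   a conjugate-symmetric spectrum is discarded.
#' @export
ifft3d <- function(ks, spacing = c(1, 1, 1)) {
  stopifnot(inherits(ks, "kspace3d"))
  x <- ks$data
  if (ks$convention == "dc_centered") x <- ifftshift3(x)
  volume3d(Re(stats::fft(x, inverse = TRUE)) / sqrt(length(x)), spacing)
}

# Circular half-grid shifts between the unshifted and centered layouts:
# fftshift3 moves DC from index 1 to index floor(n/2) + 1; ifftshift3 is
# its exact inverse (the two differ for odd sizes).
fftshift3 <- function(arr) {
  d <- dim(arr)
  idx <- lapply(d, function(n) c(seq(ceiling(n / 2) + 1, n), seq_len(ceiling(n / 2))))
  arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

ifftshift3 <- function(arr) {
  d <- dim(arr)
  idx <- lapply(d, function(n) c(seq(floor(n / 2) + 1, n), seq_len(floor(n / 2))))
  arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Convert a spectrum or mask between shift conventions
#'
#' @param x A `kspace3d` or `frequency_mask`.
#' @param convention Target convention.
#' @return The converted object.
#' @export
kshift <- function(x, convention = c("dc_at_corner", "dc_centered")) {
  convention <- match.arg(convention)
  if (x$convention == convention) return(x)
  x$data <- if (convention == "dc_centered") fftshift3(x$data) else ifftshift3(x$data)
  x$convention <- convention
  x
}

#' Build the binary frequency-domain mask
#'
#' The penalty of the training loss acts on the fine-detail (high spatial
#' frequency) part of the spectrum: the outer `outer_zero_fraction` of each
#' axis's frequency extent — contrast information — is zeroed out and the
#' rest kept. Because the transform of a reconstructed image is unshifted,
#' the kept region is the *central* box of the `dc_at_corner` array (the
#' array center holds the highest frequencies there): a band of
#' `round((1 - fraction) * N)` indices per axis centered at index
#' `floor(N / 2)` (0-based), ties resolved toward the lower index. Under
#' `dc_centered` the same frequencies sit at the array corners, so the mask
#' array is the half-grid-shifted image of the canonical box. A `radial`
#' geometry (ellipsoidal ball of relative radius `1 - fraction`) is
#' provided as an alternative to the separable box.
#'
#' @param dims Integer triple, the spectrum dimensions.
#' @param outer_zero_fraction Fraction of each axis's extent to zero out,
#'   in \[0, 1); default 0.3.
#' @param geometry `"per_axis_box"` (default) or `"radial"`.
#' @param convention Layout of the spectrum the mask will multiply.
#' @return An object of class `frequency_mask` with binary `data`,
#'   `keep_fraction` (fraction of coefficients kept), `fraction`,
#'   `geometry` and `convention`.
#' @export
build_mask <- function(dims, outer_zero_fraction = 0.3,
                       geometry = c("per_axis_box", "radial"),
                       convention = c("dc_at_corner", "dc_centered")) {
  geometry <- match.arg(geometry)
  convention <- match.arg(convention)
  if (outer_zero_fraction < 0 || outer_zero_fraction >= 1)
    stop(fdosr_error("outer_zero_fraction must be in [0, 1)", "fdosr_spec_error"))
  dims <- as.integer(dims)
  f <- outer_zero_fraction

  if (geometry == "per_axis_box") {
    axis_keep <- lapply(dims, function(n) {
      len <- floor((1 - f) * n + 0.5)
      c0 <- floor(n / 2)                      # 0-based array center
      lo <- c0 - ceiling((len - 1) / 2)       # ties include the lower index
      ind <- rep(0, n)
      if (len > 0) ind[(lo:(lo + len - 1)) + 1] <- 1
      ind
    })
    mask <- outer(outer(axis_keep[[1]], axis_keep[[2]]), axis_keep[[3]])
    dim(mask) <- dims
  } else {
    g <- coord_grids(dims)
    c0 <- floor(dims / 2) + 1                 # 1-based center
    u2 <- ((g$x - c0[1]) / (dims[1] / 2))^2 +
          ((g$y - c0[2]) / (dims[2] / 2))^2 +
          ((g$z - c0[3]) / (dims[3] / 2))^2
    mask <- (u2 <= (1 - f)^2) * 1
  }

  if (convention == "dc_centered") mask <- fftshift3(mask)
  structure(list(data = mask, keep_fraction = mean(mask), fraction = f,
                 geometry = geometry, convention = convention),
            class = "frequency_mask")
}

# Internal: return the mask array in the requested convention.
mask_in_convention <- function(mask, convention) {
  if (mask$convention == convention) return(mask$data)
  if (convention == "dc_centered") fftshift3(mask$data) else ifftshift3(mask$data)
}

# Internal: conjugate-symmetrized copy of a mask (logical AND of the mask
# with its frequency-reversed image), so that masked spectra of real
# volumes invert to real images.
conj_symmetrize <- function(mask) {
  m <- mask_in_convention(mask, "dc_at_corner")
  d <- dim(m)
  idx <- lapply(d, function(n) c(1L, rev(seq_len(n))[-n]))  # j -> (N - j) mod N
  mr <- m[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  mask$data <- m * mr
  mask$convention <- "dc_at_corner"
  mask$keep_fraction <- mean(mask$data)
  mask
}

#' Masked frequency-domain residual
#'
#' The regularization term of the training loss: the masked spectral
#' difference between prediction and ground truth, reduced to the mean
#' complex magnitude over kept coefficients. Averaging (rather than
#' summing) makes the balance set by the regularization weight independent
#' of volume size.
#'
#' @param y_hat,y `volume3d` objects (or arrays) of identical dimensions.
#' @param mask A [build_mask()] result of matching dimensions.
#' @return A nonnegative scalar; 0 iff the masked spectra agree.
#' @export
fd_residual <- function(y_hat, y, mask) {
  check_same_dims(y_hat, y)
  if (!identical(dim(mask$data), dim(vol_data(y))))
    stop(fdosr_error("mask dimensions must match the volumes", "fdosr_shape_error"))
  m <- mask_in_convention(mask, "dc_at_corner")
  n_keep <- sum(m)
  if (n_keep == 0) return(0)
  diff <- vol_data(y_hat) - vol_data(y)
  e <- stats::fft(diff) / sqrt(length(diff))
  sum(m * Mod(e)) / n_keep
}

#' Split a volume into low- and high-frequency band images
#'
#' Applies complementary masks in the frequency domain and inverts each
#' part, illustrating what the regularization acts on: the high band holds
#' fine detail (edges, thin vessels), the low band holds contrast. The box
#' mask is conjugate-symmetrized so both band images are real to machine
#' precision; the two bands sum to the input exactly.
#'
#' @param vol A `volume3d`.
#' @param fraction Outer zero fraction defining the band split, in (0, 1).
#' @return A list with `volume3d` elements `low` and `high`, plus `mask`,
#'   the symmetrized high-band mask actually applied.
#' @export
split_bands <- function(vol, fraction = 0.3) {
  vol <- as_volume3d(vol)
  if (fraction <= 0 || fraction >= 1)
    stop(fdosr_error("fraction must be in (0, 1)", "fdosr_spec_error"))
  mask <- conj_symmetrize(build_mask(dim(vol), fraction))
  ks <- fft3d(vol)
  high <- ks; high$data <- ks$data * mask$data
  low <- ks;  low$data <- ks$data * (1 - mask$data)
  list(low = ifft3d(low, vol$spacing), high = ifft3d(high, vol$spacing),
       mask = mask)
}

#' Spectral energy of a (possibly masked) spectrum
#'
#' @param ks A `kspace3d`, `frequency_mask`, or complex/numeric array.
#' @return Sum of squared magnitudes.
#' @export
spectral_energy <- function(ks) {
  x <- if (is.list(ks)) ks$data else ks
  sum(Mod(x)^2)
}
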