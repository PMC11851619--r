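#' Simulate a low-resolution acquisition
#'
#' Downsamples a high-resolution volume by an arbitrary factor `s >= 1`.
#' Output dimensions are `floor(N / s)` per axis and the nominal voxel
#' spacing is scaled by `s`. Two kernels are provided: `trilinear`
#' resampling in image space (cell-centered geometry; preserves constant
#' fields exactly), and `kspace_truncation`, which keeps only the central
#' low-frequency block of the spectrum — the classical k-space idiom for
#' acquiring at lower resolution (the result has no spectral content above
#' the Nyquist band of the low-resolution grid).
#'
#' @param hr A `volume3d`.
#' @param s Scale factor, `s >= 1`.
#' @param method `"trilinear"` (default) or `"kspace_truncation"`.
#' @return A `volume3d` of dimensions `floor(dim(hr) / s)`.
#' @export
degrade <- function(hr, s, method = c("trilinear", "kspace_truncation")) {
  method <- match.arg(method)
  hr <- as_volume3d(hr)
  if (s < 1)
    stop(fdosr_error("scale factor must be >= 1", "fdosr_spec_error"))
  out_dims <- lr_dims(dim(hr), s)
  if (any(out_dims < 8L))
    stop(fdosr_error(
      sprintf("degraded dimensions floor(N / s) = %s fall below the minimum of 8 voxels per axis",
              paste(out_dims, collapse = "x")),
      "fdosr_shape_error"))

  if (method == "trilinear") {
    out <- resample_trilinear(hr$data, out_dims)
  } else {
    n_in <- dim(hr)
    ks <- stats::fft(hr$data)                 # unscaled; dc_at_corner
    ksc <- fftshift3(ks)
    start <- floor(n_in / 2) - floor(out_dims / 2) + 1L
    keep <- lapply(1:3, function(a) seq(start[a], start[a] + out_dims[a] - 1L))
    trunc <- ksc[keep[[1]], keep[[2]], keep[[3]], drop = FALSE]
    out <- Re(stats::fft(ifftshift3(trunc), inverse = TRUE)) / prod(n_in)
  }
  volume3d(out, hr$spacing * s)
}

#' Nearest-neighbor upsampling baseline
#'
#' The classical interpolation baseline: each output voxel copies the
#' geometrically nearest source voxel under the same cell-centered mapping
#' the network's upscale step uses, so baseline and model are compared on
#' identical output grids.
#'
#' @param lr A `volume3d`.
#' @param s Scale factor, `s >= 1`.
#' @param target_dims Optional explicit output dimensions (used during
#'   evaluation against a stored ground truth); defaults to
#'   `round(dim(lr) * s)`.
#' @return A `volume3d`.
#' @export
nearest_baseline <- function(lr, s, target_dims = NULL) {
  lr <- as_volume3d(lr)
  if (s < 1)
    stop(fdosr_error("scale factor must be >= 1", "fdosr_spec_error"))
  in_dims <- dim(lr)
  if (is.null(target_dims)) target_dims <- sr_dims(in_dims, s)
  ix <- axis_nearest_index(target_dims[1], in_dims[1])
  iy <- axis_nearest_index(target_dims[2], in_dims[2])
  iz <- axis_nearest_index(target_dims[3], in_dims[3])
  volume3d(lr$data[ix, iy, iz, drop = FALSE], lr$spacing / s)
}

#' Trilinear upsampling baseline
#'
#' @inheritParams nearest_baseline
#' @return A `volume3d`.
#' @export
trilinear_baseline <- function(lr, s, target_dims = NULL) {
  lr <- as_volume3d(lr)
  if (s < 1)
    stop(fdosr_error("scale factor must be >= 1", "fdosr_spec_error"))
  if (is.null(target_dims)) target_dims <- sr_dims(dim(lr), s)
  volume3d(resample_trilinear(lr$data, as.integer(target_dims)), lr$spacing / s)
}
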