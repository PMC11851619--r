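#' Construct a 3D volume
#'
#' A `volume3d` is the package's basic container: a real-valued 3D intensity
#' array plus a physical voxel spacing in mm. Low-resolution inputs and
#' high-resolution ground-truth images are both carried in this type.
#'
#' @param data Numeric 3D array; all values must be finite.
#' @param spacing Positive numeric triple, mm per voxel along each axis.
#' @return An object of class `volume3d` with elements `data` and `spacing`.
#' @export
volume3d <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (!all(is.finite(data)))
    stop(fdosr_error("volume contains non-finite values", "fdosr_nonfinite_error"))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be a positive triple", call. = FALSE)
  structure(list(data = data, spacing = spacing), class = "volume3d")
}

#' @export
dim.volume3d <- function(x) dim(x$data)

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d voxels, spacing %s mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Coerce to a volume3d
#'
#' @param x A `volume3d`, or a numeric 3D array (unit spacing assumed).
#' @param spacing Spacing used when `x` is a bare array.
#' @return A `volume3d`.
#' @export
as_volume3d <- function(x, spacing = c(1, 1, 1)) {
  if (inherits(x, "volume3d")) return(x)
  volume3d(x, spacing)
}

#' Min-max normalize a volume to [0, 1]
#'
#' Volumes are normalized per-volume before training and before any metric
#' is computed, which fixes the PSNR data range at 1. A volume with zero
#' intensity range is clamped to \[0, 1\] but not rescaled, so a constant
#' background keeps its level.
#'
#' @param vol A `volume3d`.
#' @return A normalized `volume3d` with `min >= 0` and `max <= 1`.
#' @export
normalize_volume <- function(vol) {
  vol <- as_volume3d(vol)
  r <- range(vol$data)
  if (diff(r) > 1e-12) {
    vol$data <- (vol$data - r[1]) / diff(r)
  } else {
    vol$data[] <- pmin(pmax(vol$data, 0), 1)
  }
  vol
}

# Internal: extract the data array from a volume3d or bare array.
vol_data <- function(x) {
  if (inherits(x, "volume3d")) x$data else x
}

# Internal: named error conditions so callers can test on class.
fdosr_error <- function(msg, class) {
  errorCondition(msg, class = c(class, "fdosr_error"))
}

check_same_dims <- function(a, b, what = "volumes") {
  if (!identical(dim(vol_data(a)), dim(vol_data(b))))
    stop(fdosr_error(sprintf("%s must have identical dimensions", what),
                     "fdosr_shape_error"))
  invisible(TRUE)
}
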