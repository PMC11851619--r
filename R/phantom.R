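#' Phantom specification
#'
#' Describes a synthetic high-resolution cardiac-like phantom: thin tubular
#' structures standing in for vessels (such as coronary arteries), larger
#' ellipsoidal shell compartments standing in for chamber walls, a smooth
#' background gradient, and one of four contrast profiles standing in for
#' the four whole-heart sequences in routine clinical use (REACT, fat-sat
#' non-contrast SSFP, contrast-enhanced SSFP, and IR-prepared SSFP). The
#' profiles differ in background level, structure/background contrast sign,
#' and shell brightness.
#'
#' @param grid_size Positive integer triple of voxel dimensions (each >= 16).
#' @param n_tubes Number of tubular structures.
#' @param tube_radius_range Radius interval in voxels; lower bound >= 0.5.
#' @param n_blobs Number of ellipsoidal shell compartments.
#' @param contrast_profile One of `"react"`, `"ncssfp"`, `"ssfp"`, `"irssfp"`.
#' @param noise_sigma Gaussian noise standard deviation (intensity units),
#'   >= 0.
#' @param gradient_amplitude Amplitude of the smooth linear background
#'   gradient (intensity units). Set to 0 for a flat background.
#' @param seed Integer seed; identical spec + seed give bit-identical
#'   phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_size = c(64, 64, 64),
                         n_tubes = 4,
                         tube_radius_range = c(0.8, 2.5),
                         n_blobs = 3,
                         contrast_profile = c("react", "ncssfp", "ssfp", "irssfp"),
                         noise_sigma = 0.01,
                         gradient_amplitude = 0.05,
                         seed = 1L) {
  contrast_profile <- match.arg(contrast_profile)
  grid_size <- as.integer(grid_size)
  if (length(grid_size) != 3L || any(grid_size < 16L))
    stop(fdosr_error("grid_size components must be >= 16", "fdosr_spec_error"))
  if (length(tube_radius_range) != 2L || tube_radius_range[1] < 0.5 ||
      diff(tube_radius_range) < 0)
    stop(fdosr_error("tube_radius_range must be an interval with lower bound >= 0.5",
                     "fdosr_spec_error"))
  if (noise_sigma < 0)
    stop(fdosr_error("noise_sigma must be >= 0", "fdosr_spec_error"))
  if (n_tubes < 0 || n_blobs < 0)
    stop(fdosr_error("structure counts must be >= 0", "fdosr_spec_error"))
  structure(list(grid_size = grid_size, n_tubes = as.integer(n_tubes),
                 tube_radius_range = as.numeric(tube_radius_range),
                 n_blobs = as.integer(n_blobs),
                 contrast_profile = contrast_profile,
                 noise_sigma = as.numeric(noise_sigma),
                 gradient_amplitude = as.numeric(gradient_amplitude),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Contrast behavior of the four sequence stand-ins: background level,
# tube (vessel) contrast relative to background, and shell brightness.
contrast_profiles <- list(
  react  = list(background = 0.15, tube =  0.65, shell =  0.20),
  ncssfp = list(background = 0.30, tube =  0.50, shell =  0.35),
  ssfp   = list(background = 0.45, tube =  0.40, shell =  0.45),
  irssfp = list(background = 0.80, tube = -0.45, shell = -0.25)
)

#' Scene-building primitives
#'
#' Low-level builders used by [generate_phantom()], exposed so that scenes
#' with analytically known content (e.g. a single axis-aligned cylinder of
#' known volume) can be constructed directly.
#'
#' @param dims Integer triple of grid dimensions.
#' @param level Constant background intensity.
#' @return `blank_scene` returns a 3D array; `add_*` return the modified
#'   array.
#' @export
blank_scene <- function(dims, level = 0) {
  array(level, dim = as.integer(dims))
}

# Voxel center coordinate grids (1-based), cached per shape.
.coord_cache <- new.env(parent = emptyenv())
coord_grids <- function(dims) {
  key <- paste(dims, collapse = "_")
  if (is.null(.coord_cache[[key]])) {
    .coord_cache[[key]] <- list(
      x = array(rep(seq_len(dims[1]), times = dims[2] * dims[3]), dim = dims),
      y = array(rep(rep(seq_len(dims[2]), each = dims[1]), times = dims[3]),
                dim = dims),
      z = array(rep(seq_len(dims[3]), each = dims[1] * dims[2]), dim = dims))
  }
  .coord_cache[[key]]
}

#' @rdname blank_scene
#' @param arr 3D array to modify.
#' @param p0,p1 Segment endpoints in voxel coordinates (numeric triples).
#' @param radius Tube radius in voxels.
#' @param amplitude Intensity added inside the tube; the edge is
#'   antialiased over one voxel so the half-amplitude isosurface sits at
#'   `radius`.
#' @export
add_tube <- function(arr, p0, p1, radius, amplitude) {
  dims <- dim(arr)
  g <- coord_grids(dims)
  v <- p1 - p0
  len2 <- sum(v^2)
  if (len2 == 0) stop("tube endpoints coincide", call. = FALSE)
  # distance from each voxel center to the segment
  t <- ((g$x - p0[1]) * v[1] + (g$y - p0[2]) * v[2] + (g$z - p0[3]) * v[3]) / len2
  t <- pmin(pmax(t, 0), 1)
  d <- sqrt((g$x - (p0[1] + t * v[1]))^2 +
            (g$y - (p0[2] + t * v[2]))^2 +
            (g$z - (p0[3] + t * v[3]))^2)
  arr + amplitude * pmin(pmax(radius + 0.5 - d, 0), 1)
}

#' @rdname blank_scene
#' @param center Ellipsoid center in voxel coordinates.
#' @param semiaxes Positive triple of semi-axis lengths in voxels.
#' @param thickness Relative shell thickness (Gaussian profile width on the
#'   normalized radius).
#' @export
add_shell <- function(arr, center, semiaxes, amplitude, thickness = 0.12) {
  g <- coord_grids(dim(arr))
  u <- sqrt(((g$x - center[1]) / semiaxes[1])^2 +
            ((g$y - center[2]) / semiaxes[2])^2 +
            ((g$z - center[3]) / semiaxes[3])^2)
  arr + amplitude * exp(-((u - 1) / thickness)^2)
}

#' @rdname blank_scene
#' @param direction Numeric triple; gradient direction (need not be unit).
#' @export
add_gradient <- function(arr, direction, amplitude) {
  if (amplitude == 0) return(arr)
  g <- coord_grids(dim(arr))
  proj <- g$x * direction[1] + g$y * direction[2] + g$z * direction[3]
  r <- range(proj)
  if (diff(r) == 0) return(arr)
  arr + amplitude * ((proj - r[1]) / diff(r) - 0.5)
}

# Minimum distance between two segments (p0,p1) and (q0,q1), by projected
# coordinate descent on the convex quadratic |p0 + s u - q0 - t v|^2.
segment_distance <- function(p0, p1, q0, q1) {
  u <- p1 - p0; v <- q1 - q0; w <- p0 - q0
  a <- sum(u * u); b <- sum(u * v); cc <- sum(v * v)
  d <- sum(u * w); e <- sum(v * w)
  s <- 0.5; t <- 0.5
  for (it in 1:30) {
    s <- if (a > 0) min(max((b * t - d) / a, 0), 1) else 0
    t <- if (cc > 0) min(max((b * s + e) / cc, 0), 1) else 0
  }
  sqrt(sum((w + s * u - t * v)^2))
}

#' Generate a high-resolution phantom
#'
#' Builds a normalized (\[0, 1\]) 3D phantom containing `n_tubes`
#' well-separated tubular structures crossing the volume, `n_blobs`
#' ellipsoidal shells, a smooth background gradient, and optional Gaussian
#' noise, under the contrast profile named in the spec. Deterministic for a
#' fixed `spec$seed` (the spec seed drives an isolated RNG stream, so the
#' caller's RNG state is untouched).
#'
#' @param spec A [phantom_spec()].
#' @return A `volume3d` with unit spacing.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$grid_size
  max_r <- spec$tube_radius_range[2]
  if (spec$n_tubes > 0 && min(dims) < 4 * max_r + 8)
    stop(fdosr_error(
      sprintf("grid too small to host requested structures: min(grid_size) = %d but tubes of radius up to %.1f require at least %.0f voxels (4 * radius + 8)",
              min(dims), max_r, 4 * max_r + 8),
      "fdosr_phantom_error"))
  prof <- contrast_profiles[[spec$contrast_profile]]

  withr::with_seed(spec$seed, {
    arr <- blank_scene(dims, prof$background)
    arr <- add_gradient(arr, stats::rnorm(3), spec$gradient_amplitude)

    if (spec$n_blobs > 0) {
      for (i in seq_len(spec$n_blobs)) {
        center <- stats::runif(3, 0.3, 0.7) * dims
        semi <- stats::runif(3, 1 / 8, 1 / 5) * dims
        arr <- add_shell(arr, center, semi, prof$shell)
      }
    }

    if (spec$n_tubes > 0) {
      placed <- list()
      attempts <- 0L
      while (length(placed) < spec$n_tubes) {
        attempts <- attempts + 1L
        if (attempts > 500L)
          stop(fdosr_error(
            "grid too small to host requested structures: could not place separated tubes",
            "fdosr_phantom_error"))
        r <- stats::runif(1, spec$tube_radius_range[1], spec$tube_radius_range[2])
        ax <- sample.int(3, 1)
        margin <- r + 2
        p0 <- stats::runif(3, margin, dims - margin)
        p0[ax] <- 1
        p1 <- p0 + stats::runif(3, -1, 1) * dims / 6
        p1 <- pmin(pmax(p1, margin), dims - margin)
        p1[ax] <- dims[ax]
        ok <- TRUE
        for (tb in placed) {
          if (segment_distance(p0, p1, tb$p0, tb$p1) < r + tb$r + 2) {
            ok <- FALSE
            break
          }
        }
        if (ok) placed[[length(placed) + 1L]] <- list(p0 = p0, p1 = p1, r = r)
      }
      for (tb in placed) arr <- add_tube(arr, tb$p0, tb$p1, tb$r, prof$tube)
    }

    if (spec$noise_sigma > 0)
      arr <- arr + stats::rnorm(length(arr), sd = spec$noise_sigma)

    normalize_volume(volume3d(arr))
  })
}

#' Draw a random super-resolution factor
#'
#' Scale factors are drawn uniformly; the training protocol uses the
#' default \[2, 4\] range, including non-integer values. Uses the caller's
#' RNG stream.
#'
#' @param lo,hi Range bounds, `1 <= lo < hi`.
#' @return A single numeric scale factor.
#' @export
sample_scale <- function(lo = 2, hi = 4) {
  if (lo < 1 || lo >= hi)
    stop(fdosr_error("scale range requires 1 <= lo < hi", "fdosr_spec_error"))
  stats::runif(1, lo, hi)
}

#' Generate one training pair
#'
#' Composes the data protocol: a high-resolution phantom, a random scale
#' factor in \[2, 4\], and the degraded low-resolution counterpart.
#'
#' @param spec A [phantom_spec()].
#' @param method Degradation method passed to [degrade()].
#' @param lo,hi Scale range passed to [sample_scale()].
#' @return A list with elements `lr`, `hr` (both `volume3d`) and `s`.
#' @export
make_training_pair <- function(spec, method = "trilinear", lo = 2, hi = 4) {
  hr <- generate_phantom(spec)
  s <- sample_scale(lo, hi)
  lr <- degrade(hr, s, method = method)
  list(lr = lr, hr = hr, s = s)
}
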