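#' Grid-size rules for arbitrary scale factors
#'
#' The degradation step maps an N-voxel axis to `floor(N / s)` voxels
#' (never extrapolating beyond the field of view); super-resolution inverts
#' it with `round(M * s)` (half-up). Both modules import these two rules so
#' the shape contract lives in one place.
#'
#' @param dims Integer triple of grid dimensions.
#' @param s Scale factor, `s >= 1`.
#' @return Integer triple.
#' @export
lr_dims <- function(dims, s) as.integer(floor(dims / s))

#' @rdname lr_dims
#' @export
sr_dims <- function(dims, s) as.integer(floor(dims * s + 0.5))

# Cell-centered source coordinate of each target sample along one axis.
# Constant fields are preserved because interpolation weights sum to one
# (coordinates are clamped to the source extent).
axis_positions <- function(n_out, n_in) {
  (seq_len(n_out) - 0.5) * (n_in / n_out) - 0.5
}

# Sparse 1D linear interpolation operator (n_out x n_in).
axis_interp_matrix <- function(n_out, n_in) {
  pos <- axis_positions(n_out, n_in)
  pos <- pmin(pmax(pos, 0), n_in - 1)
  i0 <- pmin(floor(pos), n_in - 2)
  if (n_in == 1L) {
    return(Matrix::sparseMatrix(i = seq_len(n_out), j = rep(1L, n_out),
                                x = rep(1, n_out), dims = c(n_out, 1L)))
  }
  w <- pos - i0
  Matrix::sparseMatrix(
    i = rep(seq_len(n_out), 2L),
    j = c(i0 + 1, i0 + 2),
    x = c(1 - w, w),
    dims = c(n_out, n_in))
}

.interp_cache <- new.env(parent = emptyenv())

# Sparse trilinear resampling operator (prod(out_dims) x prod(in_dims)),
# separable Kronecker product of the per-axis operators; cached by shape.
interp_operator <- function(in_dims, out_dims) {
  key <- paste(c(in_dims, out_dims), collapse = "_")
  if (!is.null(.interp_cache[[key]])) return(.interp_cache[[key]])
  w1 <- axis_interp_matrix(out_dims[1], in_dims[1])
  w2 <- axis_interp_matrix(out_dims[2], in_dims[2])
  w3 <- axis_interp_matrix(out_dims[3], in_dims[3])
  op <- w3 %x% w2 %x% w1  # first index fastest
  op <- methods::as(op, "CsparseMatrix")
  .interp_cache[[key]] <- list(op = op, opt = Matrix::t(op))
  .interp_cache[[key]]
}

# Trilinear resample of a 3D array to out_dims.
resample_trilinear <- function(arr, out_dims) {
  if (identical(dim(arr), as.integer(out_dims))) return(arr)
  op <- interp_operator(dim(arr), out_dims)$op
  array(as.numeric(op %*% as.vector(arr)), dim = out_dims)
}

# Nearest-neighbor index map along one axis under the same cell-centered
# geometry as the trilinear operator.
axis_nearest_index <- function(n_out, n_in) {
  pos <- axis_positions(n_out, n_in)
  pmin(pmax(as.integer(floor(pos + 0.5)), 0L), n_in - 1L) + 1L
}
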