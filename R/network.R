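#' Encoder configuration
#'
#' The encoder is a residual dense network operating on the low-resolution
#' grid: two shallow 3D convolutions, a chain of residual dense blocks
#' (each block's layers receive the channel concatenation of all previous
#' layer outputs, followed by a 1x1x1 local fusion convolution and a local
#' residual), global feature fusion of all block outputs through two
#' convolutions, a global residual back to the first shallow convolution,
#' and a head convolution to `feature_dim` channels followed by a
#' parameter-free trilinear upscale to the target grid. There is no
#' pooling, no normalization, and no skip connection into the decoder.
#'
#' @param n_rdb Number of residual dense blocks (default 8).
#' @param layers_per_rdb Conv+ReLU layers per block (default 3).
#' @param base_channels Channel width of the trunk (default 64).
#' @param growth_channels Channels added by each dense layer (default 32).
#' @param feature_dim Per-voxel feature length produced by the head
#'   (default 128).
#' @param conv_kernel Spatial kernel size of the 3D convolutions (odd;
#'   default 3; zero padding preserves dimensions).
#' @param fusion_kernel Kernel of the fusion convolutions (default 1).
#' @return An `encoder_config` object.
#' @export
encoder_config <- function(n_rdb = 8, layers_per_rdb = 3, base_channels = 64,
                           growth_channels = 32, feature_dim = 128,
                           conv_kernel = 3, fusion_kernel = 1) {
  ok <- n_rdb >= 1 && layers_per_rdb >= 1 && feature_dim >= 1 &&
    base_channels >= 1 && growth_channels >= 1 &&
    conv_kernel %% 2 == 1 && fusion_kernel == 1
  if (!ok)
    stop(fdosr_error(paste("invalid encoder configuration: counts and widths",
                           "must be >= 1, conv_kernel odd, fusion_kernel 1"),
                     "fdosr_spec_error"))
  structure(list(n_rdb = as.integer(n_rdb),
                 layers_per_rdb = as.integer(layers_per_rdb),
                 base_channels = as.integer(base_channels),
                 growth_channels = as.integer(growth_channels),
                 feature_dim = as.integer(feature_dim),
                 conv_kernel = as.integer(conv_kernel),
                 fusion_kernel = as.integer(fusion_kernel)),
            class = "encoder_config")
}

#' Decoder configuration
#'
#' The decoder is a multi-layer perceptron applied independently to each
#' voxel's feature vector with shared weights: `n_layers - 1` linear+ReLU
#' layers followed by one final linear layer to a single intensity (no
#' final activation, so values near 0 and 1 are reachable without
#' saturation bias).
#'
#' @param n_layers Total layers including the final linear one (default 8).
#' @param hidden_width Width of the hidden layers (default 128).
#' @param output_dim Fixed at 1.
#' @return A `decoder_config` object.
#' @export
decoder_config <- function(n_layers = 8, hidden_width = 128, output_dim = 1) {
  if (!(n_layers >= 2 && output_dim == 1 && hidden_width >= 1))
    stop(fdosr_error(paste("invalid decoder configuration: n_layers >= 2,",
                           "hidden_width >= 1, output_dim fixed at 1"),
                     "fdosr_spec_error"))
  structure(list(n_layers = as.integer(n_layers),
                 hidden_width = as.integer(hidden_width),
                 output_dim = 1L),
            class = "decoder_config")
}

# Fan-in-scaled random initialization for one conv/linear parameter pair.
# `scale` shrinks the draw; residual-branch output layers use a small
# scale so each block starts close to the identity, which keeps the early
# optimization near the well-conditioned shallow linear path.
init_param <- function(n_out, fan_in, relu = TRUE, scale = 1) {
  sd <- scale * sqrt((if (relu) 2 else 1) / fan_in)
  list(w = matrix(stats::rnorm(n_out * fan_in, sd = sd), n_out, fan_in),
       b = numeric(n_out))
}

#' Initialize a super-resolution model
#'
#' Allocates encoder parameters (theta) and decoder parameters (phi) with
#' fan-in-scaled random initialization and zero biases, then imprints an
#' interpolation-aware identity path: the first shallow-conv channel is an
#' identity kernel, the residual-branch output convolutions start near
#' zero, the first head-conv channel taps that identity channel, and one
#' decoder unit passes it through unchanged. At initialization the network
#' therefore reproduces trilinear interpolation exactly (the feature
#' upscale is trilinear), and training refines from that baseline instead
#' of from noise — essential when the optimization budget is small.
#'
#' @param encoder An [encoder_config()].
#' @param decoder A [decoder_config()].
#' @param seed Optional integer; when given, initialization draws from an
#'   isolated RNG stream and the caller's RNG state is untouched.
#' @return An object of class `sr_model`.
#' @export
init_sr_model <- function(encoder = encoder_config(),
                          decoder = decoder_config(), seed = NULL) {
  build <- function() {
    e <- encoder; k3 <- e$conv_kernel^3
    enc <- list(
      shallow1 = init_param(e$base_channels, 1 * k3),
      shallow2 = init_param(e$base_channels, e$base_channels * k3),
      rdb = lapply(seq_len(e$n_rdb), function(i) {
        list(conv = lapply(seq_len(e$layers_per_rdb), function(k) {
               fan <- (e$base_channels + (k - 1) * e$growth_channels) * k3
               init_param(e$growth_channels, fan)
             }),
             fusion = init_param(
               e$base_channels,
               e$base_channels + e$layers_per_rdb * e$growth_channels,
               scale = 0.1))
      }),
      gfuse1 = init_param(e$base_channels, e$n_rdb * e$base_channels),
      gfuse2 = init_param(e$base_channels, e$base_channels * k3, scale = 0.01),
      head = init_param(e$feature_dim, e$base_channels * k3, scale = 0.1))
    d <- decoder
    widths_in <- c(e$feature_dim, rep(d$hidden_width, d$n_layers - 1))
    widths_out <- c(rep(d$hidden_width, d$n_layers - 1), d$output_dim)
    dec <- lapply(seq_len(d$n_layers), function(k)
      init_param(widths_out[k], widths_in[k], relu = k < d$n_layers))

    # Identity path: shallow1 channel 1 copies the input voxel, head
    # channel 1 taps it off the global residual, and decoder unit 1
    # passes it through every hidden layer (inputs are in [0, 1], so the
    # rectifier is transparent on this path). The final readout starts as
    # that unit plus a small random mixture of the learned features.
    center1 <- (k3 + 1) %/% 2                       # center tap, 1 input channel
    enc$shallow1$w[1, ] <- 0
    enc$shallow1$w[1, center1] <- 1
    head_col <- ((k3 - 1) %/% 2) * e$base_channels + 1
    enc$head$w[1, ] <- 0
    enc$head$w[1, head_col] <- 1
    if (d$n_layers > 1) {
      for (j in seq_len(d$n_layers - 1)) {
        dec[[j]]$w[1, ] <- 0
        dec[[j]]$w[1, 1] <- 1
      }
    }
    dec[[d$n_layers]]$w <- dec[[d$n_layers]]$w * 0.01
    dec[[d$n_layers]]$w[1, 1] <- 1

    structure(list(encoder = encoder, decoder = decoder,
                   params = list(enc = enc, dec = dec)),
              class = "sr_model")
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

# Internal conv wrapper over the compiled kernel; 1x1x1 fusions are plain
# matrix products.
conv_fw <- function(x, p, dims, k) {
  if (k == 1L) p$w %*% x + p$b
  else conv3d_fw_cpp(x, p$w, p$b, as.integer(dims), k)
}

conv_bw <- function(x, p, dy, dims, k) {
  if (k == 1L) {
    list(dx = crossprod(p$w, dy), dw = tcrossprod(dy, x), db = rowSums(dy))
  } else {
    conv3d_bw_cpp(x, p$w, dy, as.integer(dims), k)
  }
}

relu <- function(x) relu_cpp(x)

# Encoder forward pass on the low-resolution grid. x is a 1 x N matrix of
# voxel intensities; returns the feature_dim x N feature map plus (when
# keep_cache) every activation needed by the backward pass.
encoder_forward <- function(x, dims, cfg, par, keep_cache = FALSE) {
  k <- cfg$conv_kernel
  a_sh1 <- conv_fw(x, par$shallow1, dims, k)
  a_sh2 <- conv_fw(a_sh1, par$shallow2, dims, k)
  g <- a_sh2
  rdb_out <- vector("list", cfg$n_rdb)
  rdb_cache <- if (keep_cache) vector("list", cfg$n_rdb) else NULL
  for (i in seq_len(cfg$n_rdb)) {
    g0 <- g
    inp <- g0
    cs <- vector("list", cfg$layers_per_rdb)
    for (j in seq_len(cfg$layers_per_rdb)) {
      cs[[j]] <- relu(conv_fw(inp, par$rdb[[i]]$conv[[j]], dims, k))
      inp <- rbind(inp, cs[[j]])
    }
    fus <- conv_fw(inp, par$rdb[[i]]$fusion, dims, 1L)
    g <- fus + g0
    rdb_out[[i]] <- g
    if (keep_cache) rdb_cache[[i]] <- list(g0 = g0, cs = cs)
  }
  cat_g <- do.call(rbind, rdb_out)
  gf1 <- conv_fw(cat_g, par$gfuse1, dims, 1L)
  gf2 <- conv_fw(gf1, par$gfuse2, dims, k)
  glob <- gf2 + a_sh1
  feat <- conv_fw(glob, par$head, dims, k)
  res <- list(feat = feat)
  if (keep_cache)
    res$cache <- list(x = x, a_sh1 = a_sh1, a_sh2 = a_sh2, rdb = rdb_cache,
                      cat_g = cat_g, gf1 = gf1, glob = glob, dims = dims)
  res
}

# Decoder forward: shared-weight MLP over columns (voxels) of the feature
# matrix.
decoder_forward <- function(feat, cfg, par, keep_cache = FALSE) {
  hs <- if (keep_cache) vector("list", cfg$n_layers - 1L) else NULL
  h <- feat
  for (j in seq_len(cfg$n_layers - 1L)) {
    h <- relu(par[[j]]$w %*% h + par[[j]]$b)
    if (keep_cache) hs[[j]] <- h
  }
  y <- par[[cfg$n_layers]]$w %*% h + par[[cfg$n_layers]]$b
  list(y = y, hs = hs)
}

#' Encode a low-resolution volume into a per-voxel feature field
#'
#' Runs the residual dense encoder on the input grid, then trilinearly
#' resamples the feature volume to the target grid, yielding one
#' `feature_dim`-length vector per voxel of the super-resolved image.
#'
#' @param x A `volume3d`, normalized to \[0, 1\].
#' @param target_dims Integer triple of output dimensions; must be
#'   componentwise >= `dim(x)` (this network only super-resolves).
#' @param model An `sr_model` (its configs and parameters are used).
#' @return A `feature_field` with elements `data` (a `feature_dim x
#'   prod(target_dims)` matrix of per-voxel features), `dims`, `channels`
#'   and `spacing`.
#' @export
encode <- function(x, target_dims, model) {
  stopifnot(inherits(model, "sr_model"))
  x <- as_volume3d(x)
  target_dims <- as.integer(target_dims)
  if (any(target_dims < dim(x)))
    stop(fdosr_error("target_dims must be >= input dimensions: this network only super-resolves",
                     "fdosr_shape_error"))
  if (min(x$data) < -1e-8 || max(x$data) > 1 + 1e-8)
    stop(fdosr_error("input must be normalized to [0, 1]; see normalize_volume()",
                     "fdosr_spec_error"))
  ef <- encoder_forward(matrix(as.numeric(x$data), 1L), dim(x),
                        model$encoder, model$params$enc)
  feat <- upscale_features(ef$feat, dim(x), target_dims)
  structure(list(data = feat, dims = target_dims,
                 channels = model$encoder$feature_dim,
                 spacing = x$spacing * dim(x) / target_dims),
            class = "feature_field")
}

upscale_features <- function(feat, in_dims, out_dims) {
  if (identical(as.integer(in_dims), as.integer(out_dims))) return(feat)
  op <- interp_operator(as.integer(in_dims), as.integer(out_dims))
  as.matrix(feat %*% op$opt)
}

#' Feature field as a 4D array
#'
#' @param f A `feature_field`.
#' @return Array of dimensions `c(dims, channels)`.
#' @export
feature_array <- function(f) {
  array(t(f$data), dim = c(f$dims, f$channels))
}

#' Decode a feature field into an intensity volume
#'
#' Applies the shared-weight MLP independently to every voxel's feature
#' vector; identical feature vectors therefore yield identical intensities
#' wherever they occur.
#'
#' @param f A `feature_field` (or a `feature_dim x N` matrix with `dims`
#'   supplied through a `feature_field`).
#' @param model An `sr_model`.
#' @return A `volume3d`.
#' @export
decode <- function(f, model) {
  stopifnot(inherits(model, "sr_model"), inherits(f, "feature_field"))
  expected <- ncol(model$params$dec[[1]]$w)
  if (nrow(f$data) != expected)
    stop(fdosr_error(
      sprintf("feature width %d does not match decoder input width %d",
              nrow(f$data), expected), "fdosr_shape_error"))
  y <- decoder_forward(f$data, model$decoder, model$params$dec)$y
  volume3d(array(as.numeric(y), dim = f$dims), f$spacing)
}

#' Super-resolve a volume by an arbitrary factor
#'
#' Full inference path: encode on the low-resolution grid, trilinearly
#' upscale the feature volume to `round(dim(x) * s)` (or an explicit
#' `target_dims`, as used during training and evaluation against a stored
#' ground truth), and decode voxel-wise.
#'
#' @param x A normalized `volume3d`.
#' @param s Scale factor, `s >= 1` (non-integer values allowed).
#' @param model A trained (or freshly initialized) `sr_model`.
#' @param target_dims Optional explicit output dimensions.
#' @return A `volume3d` of the target dimensions.
#' @export
super_resolve <- function(x, s, model, target_dims = NULL) {
  x <- as_volume3d(x)
  if (s < 1)
    stop(fdosr_error("scale factor must be >= 1", "fdosr_spec_error"))
  if (is.null(target_dims)) target_dims <- sr_dims(dim(x), s)
  decode(encode(x, target_dims, model), model)
}

#' Inventory of the model's layer graph
#'
#' Enumerates every operator in forward order with its type, kernel and
#' channel widths, allowing the architecture to be audited: counts of
#' convolutions per stage, absence of pooling and normalization operators,
#' and absence of encoder-to-decoder skip connections (the decoder's only
#' input is the feature field).
#'
#' @param model An `sr_model`.
#' @return A data.frame with columns `stage`, `type`, `kernel`,
#'   `in_channels`, `out_channels`, `n_params`.
#' @export
layer_inventory <- function(model) {
  e <- model$encoder; d <- model$decoder
  rows <- list()
  add <- function(stage, type, kernel, cin, cout, np) {
    rows[[length(rows) + 1L]] <<- data.frame(
      stage = stage, type = type, kernel = kernel,
      in_channels = cin, out_channels = cout, n_params = np,
      stringsAsFactors = FALSE)
  }
  k <- e$conv_kernel; k3 <- k^3
  np <- function(cin, cout, kk) cout * cin * kk^3 + cout
  add("shallow", "conv3d", k, 1, e$base_channels, np(1, e$base_channels, k))
  add("shallow", "conv3d", k, e$base_channels, e$base_channels,
      np(e$base_channels, e$base_channels, k))
  for (i in seq_len(e$n_rdb)) {
    stage <- sprintf("rdb_%02d", i)
    for (j in seq_len(e$layers_per_rdb)) {
      cin <- e$base_channels + (j - 1) * e$growth_channels
      add(stage, "conv3d", k, cin, e$growth_channels,
          np(cin, e$growth_channels, k))
      add(stage, "relu", NA, e$growth_channels, e$growth_channels, 0)
    }
    cin <- e$base_channels + e$layers_per_rdb * e$growth_channels
    add(stage, "fusion_conv3d", 1, cin, e$base_channels,
        np(cin, e$base_channels, 1))
  }
  add("global_fusion", "fusion_conv3d", 1, e$n_rdb * e$base_channels,
      e$base_channels, np(e$n_rdb * e$base_channels, e$base_channels, 1))
  add("global_fusion", "conv3d", k, e$base_channels, e$base_channels,
      np(e$base_channels, e$base_channels, k))
  add("head", "conv3d", k, e$base_channels, e$feature_dim,
      np(e$base_channels, e$feature_dim, k))
  add("upscale", "trilinear_resample", NA, e$feature_dim, e$feature_dim, 0)
  widths_in <- c(e$feature_dim, rep(d$hidden_width, d$n_layers - 1))
  widths_out <- c(rep(d$hidden_width, d$n_layers - 1), d$output_dim)
  for (j in seq_len(d$n_layers)) {
    add("decoder", "linear", NA, widths_in[j], widths_out[j],
        widths_out[j] * widths_in[j] + widths_out[j])
    if (j < d$n_layers) add("decoder", "relu", NA, widths_out[j], widths_out[j], 0)
  }
  do.call(rbind, rows)
}

#' Total number of learnable parameters
#'
#' @param model An `sr_model`.
#' @return Integer count over encoder and decoder weights and biases.
#' @export
count_parameters <- function(model) {
  total <- 0L
  walk <- function(p) {
    if (is.numeric(p)) total <<- total + length(p)
    else for (q in p) walk(q)
  }
  walk(model$params)
  total
}

#' @export
print.sr_model <- function(x, ...) {
  e <- x$encoder; d <- x$decoder
  cat(sprintf("<sr_model> %d RDBs x %d layers, base %d, growth %d, features %d; decoder %d layers x %d; %s parameters\n",
              e$n_rdb, e$layers_per_rdb, e$base_channels, e$growth_channels,
              e$feature_dim, d$n_layers, d$hidden_width,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}
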