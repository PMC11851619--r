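#' Read a volume from a NIfTI-1 file
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A `volume3d` with spacing taken from the header. Files with
#'   non-finite voxels are rejected with a named error.
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop(fdosr_error(sprintf("volume file not found: %s", path),
                     "fdosr_io_error"))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop(fdosr_error(sprintf("could not parse %s: %s", path,
                                             conditionMessage(e)),
                                     "fdosr_io_error")))
  data <- array(as.numeric(img), dim = dim(img))
  if (!all(is.finite(data)))
    stop(fdosr_error(sprintf("volume %s contains non-finite voxels", path),
                     "fdosr_nonfinite_error"))
  spacing <- RNifti::pixdim(img)[1:3]
  volume3d(data, spacing)
}

#' Write a volume to a NIfTI-1 file
#'
#' Intensities are stored as float64, so a write/read round trip is
#' bit-identical; spacing is written to the header. Gzipped (`.nii.gz`)
#' and plain (`.nii`) variants are both supported.
#'
#' @param vol A `volume3d`.
#' @param path Destination path; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  vol <- as_volume3d(vol)
  if (!dir.exists(dirname(path)))
    stop(fdosr_error(sprintf("parent directory does not exist: %s",
                             dirname(path)), "fdosr_io_error"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Pipeline run configuration
#'
#' Bundles everything one end-to-end run needs: output paths, phantom
#' defaults, architecture and training configuration, the evaluation
#' factor grid, and a single global seed from which every random consumer
#' (phantom seeds, shuffling, scale draws, initialization) is derived.
#' Round-trips losslessly through YAML via [write_run_config()] /
#' [read_run_config()].
#'
#' @param output_dir Directory receiving all artifacts (corpus,
#'   checkpoints, reports, logs).
#' @param seed Global integer seed.
#' @param n_train,n_val,n_test Corpus sizes.
#' @param grid_size Phantom grid dimensions.
#' @param phantom Named list of [phantom_spec()] overrides (profile
#'   cycling is handled by [simulate_corpus()]).
#' @param training A [training_config()].
#' @param encoder An [encoder_config()].
#' @param decoder A [decoder_config()].
#' @param factors Evaluation factor grid.
#' @return A `run_config` object.
#' @export
run_config <- function(output_dir, seed = 1L, n_train = 8, n_val = 2,
                       n_test = 4, grid_size = c(32, 32, 32),
                       phantom = list(),
                       training = training_config(epochs = 10, seed = seed,
                                                  lr_initial = 1e-3),
                       encoder = encoder_config(n_rdb = 2, base_channels = 32,
                                                growth_channels = 16,
                                                feature_dim = 64),
                       decoder = decoder_config(n_layers = 4, hidden_width = 64),
                       factors = c(2, 3, 4)) {
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 n_train = as.integer(n_train), n_val = as.integer(n_val),
                 n_test = as.integer(n_test),
                 grid_size = as.integer(grid_size), phantom = phantom,
                 training = training, encoder = encoder, decoder = decoder,
                 factors = as.numeric(factors)),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$training <- unclass(x$training)
  x$training$patch_size <- x$training$patch_size  # NULL stays absent
  x$encoder <- unclass(x$encoder)
  x$decoder <- unclass(x$decoder)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  run_config(output_dir = x$output_dir, seed = x$seed, n_train = x$n_train,
             n_val = x$n_val, n_test = x$n_test, grid_size = x$grid_size,
             phantom = if (is.null(x$phantom)) list() else x$phantom,
             training = do.call(training_config, x$training),
             encoder = do.call(encoder_config, x$encoder),
             decoder = do.call(decoder_config, x$decoder),
             factors = x$factors)
}

#' Save / load a model checkpoint
#'
#' Checkpoints embed the architecture configurations alongside the
#' parameters; a JSON model card recording the seed, configurations and
#' corpus digest is written next to the checkpoint.
#'
#' @param model An `sr_model`.
#' @param path Checkpoint file path (`.rds`).
#' @param card Optional named list written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path, card = NULL) {
  saveRDS(model, path)
  if (!is.null(card)) {
    jsonlite::write_json(card, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "sr_model"))
  model
}
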