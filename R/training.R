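#' Training configuration
#'
#' Defaults follow the study protocol where stated — regularization weight
#' 1e-3, initial learning rate 1e-4 stepped every 200 epochs, 30% outer
#' mask fraction, scale factors drawn uniformly from \[2, 4\] afresh for
#' every example in every epoch — with desk-scale defaults elsewhere (200
#' epochs, learning-rate decay factor 0.5, whole-volume batches of one).
#'
#' @param lambda_reg Nonnegative frequency-regularization weight.
#' @param epochs Number of passes over the corpus.
#' @param lr_initial Initial learning rate (> 0).
#' @param lr_step_epochs Epoch cadence of learning-rate updates.
#' @param lr_gamma Multiplicative decay per step, in (0, 1].
#' @param batch_size Examples per parameter update (1 = one volume).
#' @param patch_size Optional integer triple; when set, a random
#'   high-resolution patch of this size is cut each step and the
#'   low-resolution input is derived from the patch, keeping the pair
#'   coherent at the sampled factor.
#' @param seed Integer seed controlling initialization, shuffling, and
#'   scale sampling.
#' @param mask_fraction Outer zero fraction of the frequency mask.
#' @param scale_range Bounds of the uniform scale-factor draw.
#' @param degrade_method Degradation kernel, see [degrade()].
#' @param max_steps Optional cap on total parameter updates (stops early).
#' @param clip_norm Positive global gradient-norm ceiling; gradients whose
#'   joint Euclidean norm exceeds it are rescaled onto it before the Adam
#'   update (standard stabilization for the spiky gradients of an L1
#'   objective). `Inf` disables clipping.
#' @return A `training_config` object.
#' @export
training_config <- function(lambda_reg = 1e-3, epochs = 200,
                            lr_initial = 1e-4, lr_step_epochs = 200,
                            lr_gamma = 0.5, batch_size = 1,
                            patch_size = NULL, seed = 1L,
                            mask_fraction = 0.3, scale_range = c(2, 4),
                            degrade_method = "trilinear",
                            max_steps = NULL, clip_norm = 1) {
  if (lambda_reg < 0) stop(fdosr_error("lambda_reg must be >= 0", "fdosr_spec_error"))
  if (lr_initial <= 0) stop(fdosr_error("lr_initial must be > 0", "fdosr_spec_error"))
  if (lr_gamma <= 0 || lr_gamma > 1)
    stop(fdosr_error("lr_gamma must be in (0, 1]", "fdosr_spec_error"))
  if (clip_norm <= 0)
    stop(fdosr_error("clip_norm must be > 0", "fdosr_spec_error"))
  structure(list(lambda_reg = lambda_reg, epochs = as.integer(epochs),
                 lr_initial = lr_initial,
                 lr_step_epochs = as.integer(lr_step_epochs),
                 lr_gamma = lr_gamma, batch_size = as.integer(batch_size),
                 patch_size = if (is.null(patch_size)) NULL else as.integer(patch_size),
                 seed = as.integer(seed), mask_fraction = mask_fraction,
                 scale_range = as.numeric(scale_range),
                 degrade_method = degrade_method,
                 max_steps = if (is.null(max_steps)) NULL else as.integer(max_steps),
                 clip_norm = clip_norm),
            class = "training_config")
}

#' Stepped learning-rate schedule
#'
#' `lr_initial * lr_gamma ^ floor(epoch / lr_step_epochs)` for a 0-based
#' epoch index.
#'
#' @param epoch Epoch index (0-based), >= 0.
#' @param cfg A [training_config()].
#' @return The learning rate at that epoch.
#' @export
lr_at_epoch <- function(epoch, cfg) {
  stopifnot(epoch >= 0)
  cfg$lr_initial * cfg$lr_gamma^floor(epoch / cfg$lr_step_epochs)
}

# Random coherent patch crop of a high-resolution volume.
crop_patch <- function(hr, patch) {
  d <- dim(hr)
  patch <- pmin(patch, d)
  lo <- vapply(1:3, function(a)
    if (d[a] > patch[a]) sample.int(d[a] - patch[a] + 1L, 1L) else 1L,
    integer(1))
  volume3d(hr$data[lo[1]:(lo[1] + patch[1] - 1L),
                   lo[2]:(lo[2] + patch[2] - 1L),
                   lo[3]:(lo[3] + patch[3] - 1L), drop = FALSE], hr$spacing)
}

#' Train a super-resolution model
#'
#' Stochastic minimization of the composite L1 + frequency-domain loss
#' with Adam. Each step draws a fresh scale factor uniformly from
#' `cfg$scale_range`, degrades one high-resolution volume to its
#' low-resolution counterpart, super-resolves it back onto the stored
#' high-resolution grid (so the loss is always well-posed), and updates
#' both parameter sets. The frequency mask is rebuilt per target grid size
#' and cached by dimensions. The run is fully reproducible from
#' `cfg$seed`.
#'
#' Training aborts with a named `fdosr_divergence_error` when the loss
#' becomes non-finite, or exceeds 1000 times its initial value for 10
#' consecutive epochs.
#'
#' @param corpus List of normalized high-resolution `volume3d` objects.
#' @param cfg A [training_config()].
#' @param encoder,decoder Architecture configurations.
#' @param validation Optional list of held-out volumes; when given, mean
#'   PSNR at `validation_factor` is computed every `cfg$lr_step_epochs`
#'   epochs (and at the end), and the best-scoring parameters are kept.
#' @param validation_factor Scale factor used for validation scoring.
#' @return A list of class `sr_training` with elements `model` (final
#'   parameters), `best_model` (best validation PSNR, or final when no
#'   validation set), `history` (per-epoch data.frame with the loss terms,
#'   learning rate and sampled scale factors), and `validation`
#'   (data.frame of validation scores, possibly empty).
#' @export
train <- function(corpus, cfg = training_config(),
                  encoder = encoder_config(), decoder = decoder_config(),
                  validation = NULL, validation_factor = 2) {
  if (length(corpus) == 0)
    stop(fdosr_error("corpus must be nonempty", "fdosr_spec_error"))
  corpus <- lapply(corpus, as_volume3d)

  set.seed(cfg$seed)
  model <- init_sr_model(encoder, decoder)
  opt <- adam_state(model$params)

  mask_cache <- new.env(parent = emptyenv())
  get_mask <- function(dims) {
    key <- paste(dims, collapse = "_")
    if (is.null(mask_cache[[key]]))
      mask_cache[[key]] <- build_mask(dims, cfg$mask_fraction)
    mask_cache[[key]]
  }

  n <- length(corpus)
  history <- vector("list", cfg$epochs)
  all_scales <- vector("list", cfg$epochs)
  val_rows <- list()
  best <- list(psnr = -Inf, params = model$params)
  initial_loss <- NA_real_
  bad_epochs <- 0L
  steps <- 0L
  done <- FALSE

  score_validation <- function(epoch) {
    ps <- vapply(validation, function(hr) {
      lr_vol <- degrade(hr, validation_factor, method = cfg$degrade_method)
      lr_vol$data <- pmin(pmax(lr_vol$data, 0), 1)
      psnr(super_resolve(lr_vol, validation_factor, model,
                         target_dims = dim(hr)), hr)
    }, numeric(1))
    mean(ps[is.finite(ps)])
  }

  for (epoch in seq_len(cfg$epochs)) {
    lr_now <- lr_at_epoch(epoch - 1L, cfg)
    order <- sample.int(n)
    ep_scales <- numeric(0)
    ep_loss <- ep_data <- ep_reg <- numeric(0)

    for (idx in order) {
      hr <- corpus[[idx]]
      if (!is.null(cfg$patch_size)) hr <- crop_patch(hr, cfg$patch_size)
      s <- sample_scale(cfg$scale_range[1], cfg$scale_range[2])
      lr_vol <- degrade(hr, s, method = cfg$degrade_method)
      lr_vol$data <- pmin(pmax(lr_vol$data, 0), 1)

      fb <- sr_forward_backward(lr_vol, hr, model, get_mask(dim(hr)),
                                cfg$lambda_reg)
      if (!is.finite(fb$total))
        stop(fdosr_error(
          sprintf("training diverged: non-finite loss at epoch %d, step %d",
                  epoch, steps + 1L), "fdosr_divergence_error"))
      grads <- clip_gradients(fb$grads, cfg$clip_norm)
      upd <- adam_update(model$params, grads, opt, lr_now)
      model$params <- upd$params
      opt <- upd$state

      steps <- steps + 1L
      ep_scales <- c(ep_scales, s)
      ep_loss <- c(ep_loss, fb$total)
      ep_data <- c(ep_data, fb$data_term)
      ep_reg <- c(ep_reg, fb$reg_term)
      if (is.na(initial_loss)) initial_loss <- fb$total
      if (!is.null(cfg$max_steps) && steps >= cfg$max_steps) {
        done <- TRUE
        break
      }
    }

    history[[epoch]] <- data.frame(
      epoch = epoch, loss = mean(ep_loss), data_term = mean(ep_data),
      reg_term = mean(ep_reg), lr = lr_now, n_steps = length(ep_loss),
      mean_scale = mean(ep_scales))
    all_scales[[epoch]] <- ep_scales

    if (mean(ep_loss) > 1e3 * initial_loss) {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= 10L)
        stop(fdosr_error(
          sprintf("training diverged: loss exceeded 1000x its initial value for %d consecutive epochs",
                  bad_epochs), "fdosr_divergence_error"))
    } else {
      bad_epochs <- 0L
    }

    if (!is.null(validation) &&
        (epoch %% cfg$lr_step_epochs == 0L || epoch == cfg$epochs || done)) {
      vp <- score_validation(epoch)
      val_rows[[length(val_rows) + 1L]] <-
        data.frame(epoch = epoch, psnr = vp)
      if (is.finite(vp) && vp > best$psnr)
        best <- list(psnr = vp, params = model$params)
    }
    if (done) break
  }

  keep <- !vapply(history, is.null, logical(1))
  history <- do.call(rbind, history[keep])
  attr(history, "scales") <- all_scales[keep]   # full per-epoch scale draws
  best_model <- model
  if (!is.null(validation) && is.finite(best$psnr))
    best_model$params <- best$params
  structure(list(model = model, best_model = best_model, history = history,
                 validation = if (length(val_rows)) do.call(rbind, val_rows)
                              else data.frame(epoch = integer(), psnr = numeric()),
                 config = cfg, steps = steps),
            class = "sr_training")
}

#' K-fold cross-validation splits
#'
#' Partitions `1:n_items` into `k` folds whose validation sets are
#' disjoint, cover every index exactly once, and differ in size by at most
#' one.
#'
#' @param n_items Number of items.
#' @param k Number of folds, `2 <= k <= n_items`.
#' @param seed Integer seed for the shuffle.
#' @return A list of `k` lists with integer elements `train` and `val`.
#' @export
kfold_split <- function(n_items, k, seed = 1L) {
  if (k < 2 || k > n_items)
    stop(fdosr_error("k must satisfy 2 <= k <= n_items", "fdosr_spec_error"))
  perm <- withr::with_seed(seed, sample.int(n_items))
  sizes <- rep(floor(n_items / k), k)
  extra <- n_items %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_len(k), function(i) {
    val <- sort(perm[starts[i]:ends[i]])
    list(train = sort(setdiff(seq_len(n_items), val)), val = val)
  })
}
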