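# Independent reference implementations used as oracles. These are written
# naively (explicit loops, textbook formulas) on purpose: they share no code
# with the package internals they check.

# Dense 3D DFT by direct summation, orthonormal scaling (divide by sqrt(N)).
ref_dft3 <- function(x) {
  d <- dim(x)
  out <- array(0 + 0i, d)
  for (k1 in 0:(d[1] - 1)) for (k2 in 0:(d[2] - 1)) for (k3 in 0:(d[3] - 1)) {
    acc <- 0 + 0i
    for (n1 in 0:(d[1] - 1)) for (n2 in 0:(d[2] - 1)) for (n3 in 0:(d[3] - 1)) {
      ph <- -2i * pi * (k1 * n1 / d[1] + k2 * n2 / d[2] + k3 * n3 / d[3])
      acc <- acc + x[n1 + 1, n2 + 1, n3 + 1] * exp(ph)
    }
    out[k1 + 1, k2 + 1, k3 + 1] <- acc
  }
  out / sqrt(prod(d))
}

# Composite loss by direct summation: mean |dy| plus lambda times the mean
# magnitude of the dense-DFT difference over kept coefficients.
ref_composite_loss <- function(y_hat, y, mask_arr, lambda) {
  data_term <- mean(abs(y_hat - y))
  ek <- ref_dft3(y_hat - y)
  n_keep <- sum(mask_arr)
  reg <- if (n_keep > 0) sum(mask_arr * Mod(ek)) / n_keep else 0
  list(total = data_term + lambda * reg, data_term = data_term, reg_term = reg)
}

# Brute-force kept-coefficient census for the canonical per-axis box mask:
# per axis, a band of round((1 - f) * n) indices centered on the 0-based
# index floor(n / 2), ties toward the lower index.
ref_mask_census <- function(dims, f) {
  keep_axis <- function(n) {
    len <- floor((1 - f) * n + 0.5)
    c0 <- floor(n / 2)
    lo <- c0 - ceiling((len - 1) / 2)
    (0:(n - 1)) >= lo & (0:(n - 1)) <= lo + len - 1
  }
  count <- 0L
  for (i in which(keep_axis(dims[1]))) for (j in which(keep_axis(dims[2])))
    for (k in which(keep_axis(dims[3]))) count <- count + 1L
  count
}

# Direct windowed-statistics SSIM: loop over every valid window position,
# compute Gaussian-weighted moments explicitly.
ref_ssim3d <- function(a, b, data_range = 1, window = 7L, sigma = 1.5) {
  half <- (window - 1) / 2
  k1 <- exp(-((-half):half)^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  w <- outer(outer(k1, k1), k1)
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  d <- dim(a)
  vals <- c()
  for (i in 1:(d[1] - window + 1)) for (j in 1:(d[2] - window + 1))
    for (k in 1:(d[3] - window + 1)) {
      ax <- a[i:(i + window - 1), j:(j + window - 1), k:(k + window - 1)]
      bx <- b[i:(i + window - 1), j:(j + window - 1), k:(k + window - 1)]
      mx <- sum(w * ax); my <- sum(w * bx)
      sxx <- sum(w * ax * ax) - mx^2
      syy <- sum(w * bx * bx) - my^2
      sxy <- sum(w * ax * bx) - mx * my
      vals <- c(vals, ((2 * mx * my + c1) * (2 * sxy + c2)) /
                      ((mx^2 + my^2 + c1) * (sxx + syy + c2)))
    }
  mean(vals)
}

ref_psnr <- function(a, b, data_range = 1) {
  m <- mean((a - b)^2)
  if (m == 0) Inf else 10 * log10(data_range^2 / m)
}

# Shared tiny architecture for fast unit tests.
unit_encoder <- function() encoder_config(n_rdb = 2, layers_per_rdb = 2,
                                          base_channels = 4,
                                          growth_channels = 3, feature_dim = 5)
unit_decoder <- function() decoder_config(n_layers = 3, hidden_width = 6)

# Desk-scale study configuration used by the stochastic learning checks.
study_encoder <- function() encoder_config(n_rdb = 2, base_channels = 32,
                                           growth_channels = 8,
                                           feature_dim = 32)
study_decoder <- function() decoder_config(n_layers = 4, hidden_width = 32)
study_training <- function(seed, lambda_reg = 1e-3) {
  training_config(lambda_reg = lambda_reg, epochs = 13, lr_initial = 3e-4,
                  lr_step_epochs = 3, lr_gamma = 0.5, seed = seed,
                  max_steps = 200)
}

# Trained-model cache shared across the stochastic acceptance checks (the
# regularized models are reused for both the learning comparison and the
# matched-pair residual comparison, halving the training budget).
.study_cache <- new.env(parent = emptyenv())

study_corpora <- function() {
  if (is.null(.study_cache$corpora)) {
    .study_cache$corpora <- list(
      train = simulate_corpus(16, grid_size = c(32, 32, 32), seed = 1),
      heldout = simulate_corpus(8, grid_size = c(32, 32, 32), seed = 2001))
  }
  .study_cache$corpora
}

study_model <- function(seed, lambda_reg) {
  key <- sprintf("m_%d_%g", seed, lambda_reg)
  if (is.null(.study_cache[[key]])) {
    corp <- study_corpora()
    fit <- train(corp$train, study_training(seed, lambda_reg),
                 study_encoder(), study_decoder())
    .study_cache[[key]] <- fit$model
  }
  .study_cache[[key]]
}

study_seeds <- 101:105

# Mean held-out PSNR of a method (sr_model or function) at one factor.
mean_heldout_psnr <- function(method, corpus, s) {
  mean(vapply(corpus, function(hr) {
    lr <- degrade(hr, s)
    lr$data <- pmin(pmax(lr$data, 0), 1)
    pred <- if (inherits(method, "sr_model"))
      super_resolve(lr, s, method, target_dims = dim(hr))
    else method(lr, s, dim(hr))
    psnr(pred, hr)
  }, numeric(1)))
}
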