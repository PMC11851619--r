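test_that("composite_loss matches the dense-DFT oracle on 2^3 pairs", {
  mask <- build_mask(c(2, 2, 2), 0.3)
  # enumerate all binary prediction volumes against two fixed targets
  targets <- list(array(0, c(2, 2, 2)),
                  array(c(1, 0, 1, 1, 0, 0, 1, 0) * 0.5, c(2, 2, 2)))
  for (y in targets) {
    for (bits in 0:255) {
      y_hat <- array(as.numeric(intToBits(bits)[1:8]), c(2, 2, 2))
      got <- composite_loss(y_hat, y, mask, lambda_reg = 1e-3)
      want <- ref_composite_loss(y_hat, y, mask$data, 1e-3)
      expect_equal(got$total, want$total, tolerance = 1e-10)
      expect_equal(got$reg_term, want$reg_term, tolerance = 1e-10)
    }
  }
})

test_that("composite_loss is additive in lambda and zero only at equality", {
  set.seed(71)
  y <- array(runif(8^3), c(8, 8, 8))
  y_hat <- y + array(rnorm(8^3, sd = 0.05), c(8, 8, 8))
  mask <- build_mask(c(8, 8, 8), 0.3)
  l0 <- composite_loss(y_hat, y, mask, 0)
  l1 <- composite_loss(y_hat, y, mask, 0.7)
  expect_equal(l1$total, l0$data_term + 0.7 * l0$reg_term, tolerance = 1e-12)
  expect_gt(l1$total, 0)
  leq <- composite_loss(y, y, mask, 0.7)
  expect_identical(leq$total, 0)
  expect_error(composite_loss(y_hat, y, mask, -1), class = "fdosr_spec_error")
})

test_that("fd_residual is a pseudometric on random triples", {
  set.seed(72)
  mask <- build_mask(c(8, 8, 8), 0.3)
  for (i in 1:5) {
    a <- array(rnorm(8^3), c(8, 8, 8))
    b <- array(rnorm(8^3), c(8, 8, 8))
    cc <- array(rnorm(8^3), c(8, 8, 8))
    expect_equal(fd_residual(a, b, mask), fd_residual(b, a, mask),
                 tolerance = 1e-12)
    expect_lte(fd_residual(a, cc, mask),
               fd_residual(a, b, mask) + fd_residual(b, cc, mask) + 1e-12)
  }
})

test_that("fd_residual agrees across spectrum conventions", {
  set.seed(73)
  a <- array(rnorm(10^3), c(10, 10, 10))
  b <- array(rnorm(10^3), c(10, 10, 10))
  r1 <- fd_residual(a, b, build_mask(c(10, 10, 10), 0.3))
  r2 <- fd_residual(a, b, build_mask(c(10, 10, 10), 0.3,
                                     convention = "dc_centered"))
  expect_equal(r1, r2, tolerance = 1e-6)
})

test_that("the stepped learning-rate schedule matches its formula", {
  cfg <- training_config(lr_initial = 1e-4, lr_step_epochs = 200,
                         lr_gamma = 0.5)
  expect_equal(lr_at_epoch(0, cfg), 1e-4)
  expect_equal(lr_at_epoch(199, cfg), 1e-4)
  expect_equal(lr_at_epoch(200, cfg), 5e-5)
  expect_equal(lr_at_epoch(400, cfg), 2.5e-5)
  cfg2 <- training_config(lr_initial = 3e-4, lr_step_epochs = 3,
                          lr_gamma = 0.5)
  expect_equal(lr_at_epoch(11, cfg2), 3e-4 * 0.5^3)
})

test_that("training_config validates its fields", {
  expect_error(training_config(lambda_reg = -1), class = "fdosr_spec_error")
  expect_error(training_config(lr_initial = 0), class = "fdosr_spec_error")
  expect_error(training_config(lr_gamma = 0), class = "fdosr_spec_error")
  expect_error(training_config(lr_gamma = 1.5), class = "fdosr_spec_error")
  expect_error(training_config(clip_norm = 0), class = "fdosr_spec_error")
})

test_that("a short training run descends and is bit-reproducible", {
  corpus <- simulate_corpus(2, grid_size = c(24, 24, 24), seed = 5)
  cfg <- training_config(epochs = 8, lr_initial = 3e-4, lr_step_epochs = 3,
                         lr_gamma = 0.5, seed = 9, max_steps = 16,
                         scale_range = c(2, 3))
  fit1 <- train(corpus, cfg, unit_encoder(), unit_decoder())
  fit2 <- train(corpus, cfg, unit_encoder(), unit_decoder())
  expect_identical(fit1$model$params, fit2$model$params)
  expect_identical(fit1$history$loss, fit2$history$loss)
  expect_lt(mean(tail(fit1$history$loss, 2)), mean(head(fit1$history$loss, 2)))
  expect_identical(fit1$steps, 16L)
  # the recorded scale draws cover the configured range
  scales <- unlist(attr(fit1$history, "scales"))
  expect_length(scales, 16L)
  expect_true(all(scales >= 2 & scales <= 4))
})

test_that("training with lambda zero records an identically zero penalty", {
  corpus <- simulate_corpus(1, grid_size = c(24, 24, 24), seed = 6)
  cfg <- training_config(lambda_reg = 0, epochs = 2, lr_initial = 3e-4,
                         seed = 9, max_steps = 4, scale_range = c(2, 3))
  fit <- train(corpus, cfg, unit_encoder(), unit_decoder())
  expect_true(all(fit$history$loss == fit$history$data_term))
  expect_true(all(fit$history$reg_term >= 0))
})

test_that("validation scoring selects the best checkpoint", {
  corpus <- simulate_corpus(2, grid_size = c(24, 24, 24), seed = 7)
  val <- simulate_corpus(1, grid_size = c(24, 24, 24), seed = 30)
  cfg <- training_config(epochs = 4, lr_initial = 3e-4, lr_step_epochs = 2,
                         seed = 9, max_steps = 8, scale_range = c(2, 3))
  fit <- train(corpus, cfg, unit_encoder(), unit_decoder(), validation = val)
  expect_gt(nrow(fit$validation), 0)
  expect_true(all(is.finite(fit$validation$psnr)))
  expect_s3_class(fit, "sr_training")
})

test_that("an unstable configuration raises the named divergence error", {
  corpus <- simulate_corpus(1, grid_size = c(24, 24, 24), seed = 8)
  cfg <- training_config(lambda_reg = 10, epochs = 40, lr_initial = 50,
                         seed = 9, clip_norm = Inf, scale_range = c(2, 3))
  expect_error(train(corpus, cfg, unit_encoder(), unit_decoder()),
               class = "fdosr_divergence_error")
})

test_that("training on an empty corpus is rejected", {
  expect_error(train(list(), training_config()), class = "fdosr_spec_error")
})

test_that("k-fold splits partition the items with balanced folds", {
  folds <- kfold_split(10, 3, seed = 2)
  vals <- lapply(folds, `[[`, "val")
  expect_identical(sort(unlist(vals)), 1:10)
  sizes <- lengths(vals)
  expect_lte(max(sizes) - min(sizes), 1L)
  for (f in folds) {
    expect_identical(sort(c(f$train, f$val)), 1:10)
    expect_length(intersect(f$train, f$val), 0)
  }
  expect_error(kfold_split(3, 5), class = "fdosr_spec_error")
  # reproducible for a seed
  expect_identical(kfold_split(10, 3, seed = 2), folds)
})
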