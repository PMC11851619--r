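test_that("config constructors enforce their invariants", {
  expect_s3_class(encoder_config(), "encoder_config")
  expect_error(encoder_config(n_rdb = 0), class = "fdosr_spec_error")
  expect_error(encoder_config(conv_kernel = 2), class = "fdosr_spec_error")
  expect_error(decoder_config(n_layers = 0), class = "fdosr_spec_error")
  expect_error(decoder_config(hidden_width = 0), class = "fdosr_spec_error")
})

test_that("initialization is reproducible from a seed and leaves the RNG alone", {
  m1 <- init_sr_model(unit_encoder(), unit_decoder(), seed = 4)
  m2 <- init_sr_model(unit_encoder(), unit_decoder(), seed = 4)
  expect_identical(m1$params, m2$params)
  set.seed(123)
  draw <- runif(1)
  set.seed(123)
  invisible(init_sr_model(unit_encoder(), unit_decoder(), seed = 4))
  expect_identical(runif(1), draw)
})

test_that("the untrained network reproduces trilinear interpolation closely", {
  # the interpolation-aware initialization makes the identity path exact;
  # the only deviations come from the deliberately small random components
  mod <- init_sr_model(study_encoder(), study_decoder(), seed = 6)
  hr <- generate_phantom(phantom_spec(grid_size = c(24, 24, 24), seed = 8))
  lr <- degrade(hr, 2)
  lr$data <- pmin(pmax(lr$data, 0), 1)
  y0 <- super_resolve(lr, 2, mod, target_dims = dim(hr))
  tri <- trilinear_baseline(lr, 2, dim(hr))
  expect_lt(max(abs(y0$data - tri$data)), 0.1)
})

test_that("super_resolve produces the rounded output grid for arbitrary scales", {
  mod <- init_sr_model(unit_encoder(), unit_decoder(), seed = 1)
  x <- normalize_volume(volume3d(array(runif(12^3), c(12, 12, 12))))
  for (s in c(2, 2.5, 3.3, 4)) {
    y <- super_resolve(x, s, mod)
    expect_identical(dim(y), as.integer(floor(12 * s + 0.5)) * c(1L, 1L, 1L))
    expect_true(all(is.finite(y$data)))
  }
  y <- super_resolve(x, 2.5, mod, target_dims = c(31, 29, 30))
  expect_identical(dim(y), c(31L, 29L, 30L))
})

test_that("encode/decode stages compose to super_resolve", {
  mod <- init_sr_model(unit_encoder(), unit_decoder(), seed = 2)
  x <- normalize_volume(volume3d(array(runif(10^3), c(10, 10, 10))))
  f <- encode(x, c(15, 15, 15), mod)
  expect_identical(f$channels, unit_encoder()$feature_dim)
  expect_identical(ncol(f$data), 3375L)
  y <- decode(f, mod)
  expect_equal(y$data, super_resolve(x, 1.5, mod)$data)
  fa <- feature_array(f)
  expect_identical(dim(fa), c(15L, 15L, 15L, unit_encoder()$feature_dim))
})

test_that("the layer inventory matches the prescribed architecture exactly", {
  mod <- init_sr_model(seed = 1)     # full-size default configuration
  inv <- layer_inventory(mod)

  # 8 residual dense blocks of 3 conv+ReLU layers and one 1x1x1 fusion
  rdb_convs <- inv[inv$type == "conv3d" & grepl("^rdb", inv$stage), ]
  expect_identical(nrow(rdb_convs), 8L * 3L)
  fusions <- inv[inv$type == "fusion_conv3d" & grepl("^rdb", inv$stage), ]
  expect_identical(nrow(fusions), 8L)
  expect_true(all(fusions$kernel == 1))

  # 2 shallow convs, 2 global-fusion convs, head conv to 128 channels
  expect_identical(sum(inv$stage == "shallow" & inv$type == "conv3d"), 2L)
  expect_identical(sum(grepl("^global_fusion", inv$stage)), 2L)
  head_row <- inv[inv$stage == "head", ]
  expect_identical(head_row$out_channels[1], 128L)

  # decoder: 8 linear layers (7 hidden + readout), shared across voxels
  expect_identical(sum(inv$type == "linear"), 8L)

  # nothing else: no pooling, no normalization layers, no skip modules
  expect_true(all(inv$type %in% c("conv3d", "fusion_conv3d", "relu",
                                  "trilinear_resample", "linear")))

  # dense connectivity: conv j inside an RDB sees base + (j-1) * growth
  expect_equal(rdb_convs$in_channels[1:3], c(64, 96, 128))
})

test_that("the parameter count matches the closed-form formula", {
  e <- encoder_config(); d <- decoder_config(); k3 <- 27
  n_enc <- (e$base_channels * k3 + e$base_channels) +                       # shallow1
    (e$base_channels^2 * k3 + e$base_channels) +                            # shallow2
    e$n_rdb * (sum(sapply(seq_len(e$layers_per_rdb), function(j)
      e$growth_channels * (e$base_channels + (j - 1) * e$growth_channels) * k3 +
        e$growth_channels)) +
      e$base_channels * (e$base_channels + e$layers_per_rdb * e$growth_channels) +
        e$base_channels) +                                                  # fusion
    (e$base_channels * e$n_rdb * e$base_channels + e$base_channels) +       # gfuse1
    (e$base_channels^2 * k3 + e$base_channels) +                            # gfuse2
    (e$feature_dim * e$base_channels * k3 + e$feature_dim)                  # head
  widths_in <- c(e$feature_dim, rep(d$hidden_width, d$n_layers - 1))
  widths_out <- c(rep(d$hidden_width, d$n_layers - 1), 1)
  n_dec <- sum(widths_in * widths_out + widths_out)

  mod <- init_sr_model(e, d, seed = 1)
  expect_equal(count_parameters(mod), n_enc + n_dec)
  expect_equal(sum(layer_inventory(mod)$n_params), n_enc + n_dec)
})

test_that("every parameter group receives gradient after one backward pass", {
  mod <- init_sr_model(unit_encoder(), unit_decoder(), seed = 3)
  set.seed(61)
  x <- normalize_volume(volume3d(array(runif(6^3), c(6, 6, 6))))
  hr <- normalize_volume(volume3d(array(runif(9^3), c(9, 9, 9))))
  fb <- fdosr:::sr_forward_backward(x, hr, mod, build_mask(c(9, 9, 9), 0.3),
                                    1e-3)
  leaves <- rapply(fb$grads, function(g) sum(abs(g)), how = "unlist")
  weight_leaves <- leaves[grepl("\\.w$|\\bw$", names(leaves))]
  expect_true(all(weight_leaves > 0))
})

test_that("super_resolve rejects shrinking targets and unnormalized input", {
  mod <- init_sr_model(unit_encoder(), unit_decoder(), seed = 1)
  x <- normalize_volume(volume3d(array(runif(10^3), c(10, 10, 10))))
  expect_error(super_resolve(x, 2, mod, target_dims = c(8, 8, 8)),
               class = "fdosr_shape_error")
  bad <- volume3d(array(runif(10^3) * 3, c(10, 10, 10)))
  expect_error(super_resolve(bad, 2, mod), class = "fdosr_spec_error")
})

test_that("decode rejects feature fields of mismatched width", {
  mod <- init_sr_model(unit_encoder(), unit_decoder(), seed = 1)
  x <- normalize_volume(volume3d(array(runif(8^3), c(8, 8, 8))))
  f <- encode(x, c(12, 12, 12), mod)
  other <- init_sr_model(encoder_config(n_rdb = 2, layers_per_rdb = 2,
                                        base_channels = 4, growth_channels = 3,
                                        feature_dim = 7),
                         unit_decoder(), seed = 1)
  expect_error(decode(f, other), class = "fdosr_shape_error")
})
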