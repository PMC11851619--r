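# Hand-derived reverse-mode differentiation of the encoder/decoder graph.
# The graph is small and fixed, so gradients are propagated explicitly in
# reverse topological order rather than through a generic autodiff tape.

#' Composite training loss
#'
#' The minimization objective: an L1 data-consistency term in the image
#' domain (mean absolute voxel difference, no mask) plus `lambda_reg`
#' times the frequency-domain penalty, the L1 norm of the masked spectral
#' difference reduced to a mean over kept coefficients (see
#' [fd_residual()]).
#'
#' @param y_hat,y Prediction and ground truth, identical dimensions.
#' @param mask A [build_mask()] result matching the volume dimensions.
#' @param lambda_reg Nonnegative regularization weight (default 1e-3).
#' @return A list with `total`, `data_term` and `reg_term`;
#'   `total = data_term + lambda_reg * reg_term`.
#' @export
composite_loss <- function(y_hat, y, mask, lambda_reg = 1e-3) {
  check_same_dims(y_hat, y)
  if (lambda_reg < 0)
    stop(fdosr_error("lambda_reg must be >= 0", "fdosr_spec_error"))
  data_term <- mean(abs(vol_data(y_hat) - vol_data(y)))
  reg_term <- fd_residual(y_hat, y, mask)
  list(total = data_term + lambda_reg * reg_term,
       data_term = data_term, reg_term = reg_term)
}

# Gradient of the composite loss with respect to the prediction. For the
# frequency term R = mean_{mask} |E_k| with E the orthonormal transform of
# the (real) error field, the gradient is Re(IFFT(mask * E / |E|)) / M,
# with the subgradient 0 taken at E_k = 0.
loss_and_grad <- function(y_hat_arr, y_arr, mask, lambda_reg) {
  e <- y_hat_arr - y_arr
  n <- length(e)
  data_term <- mean(abs(e))
  d <- sign(e) / n
  m <- mask_in_convention(mask, "dc_at_corner")
  n_keep <- sum(m)
  ek <- stats::fft(e) / sqrt(n)
  a <- Mod(ek)
  reg_term <- if (n_keep > 0) sum(m * a) / n_keep else 0
  if (lambda_reg > 0 && n_keep > 0) {
    w <- m * ek / pmax(a, 1e-30)
    w[a == 0] <- 0
    g <- Re(stats::fft(w, inverse = TRUE)) / sqrt(n) / n_keep
    d <- d + lambda_reg * g
  }
  list(total = data_term + lambda_reg * reg_term, data_term = data_term,
       reg_term = reg_term, grad = d)
}

# Zero gradient tree with the same shape as the parameters.
zero_like <- function(p) rapply(p, function(x) x * 0, how = "replace")

# Full forward + backward pass for one training example. Returns the loss
# components and the gradient tree (same structure as model$params).
sr_forward_backward <- function(x, hr, model, mask, lambda_reg) {
  enc_cfg <- model$encoder; dec_cfg <- model$decoder
  par <- model$params
  in_dims <- dim(x); out_dims <- dim(hr)
  k <- enc_cfg$conv_kernel
  L <- enc_cfg$layers_per_rdb
  base <- enc_cfg$base_channels

  ef <- encoder_forward(matrix(as.numeric(x$data), 1L), in_dims, enc_cfg,
                        par$enc, keep_cache = TRUE)
  cache <- ef$cache
  feat_hr <- upscale_features(ef$feat, in_dims, out_dims)
  df <- decoder_forward(feat_hr, dec_cfg, par$dec, keep_cache = TRUE)
  y_hat <- array(as.numeric(df$y), dim = out_dims)

  ls <- loss_and_grad(y_hat, hr$data, mask, lambda_reg)

  grads <- zero_like(par)

  # ---- decoder backward ----
  dy <- matrix(as.numeric(ls$grad), 1L)
  nl <- dec_cfg$n_layers
  h_prev <- if (nl >= 2) df$hs[[nl - 1L]] else feat_hr
  grads$dec[[nl]]$w <- tcrossprod(dy, h_prev)
  grads$dec[[nl]]$b <- rowSums(dy)
  dh <- crossprod(par$dec[[nl]]$w, dy)
  for (j in seq(nl - 1L, 1L)) {
    dpre <- drelu_cpp(dh, df$hs[[j]])
    inp <- if (j > 1L) df$hs[[j - 1L]] else feat_hr
    grads$dec[[j]]$w <- tcrossprod(dpre, inp)
    grads$dec[[j]]$b <- rowSums(dpre)
    dh <- crossprod(par$dec[[j]]$w, dpre)
  }
  d_feat_hr <- dh

  # ---- upscale backward ----
  d_feat <- if (identical(in_dims, out_dims)) d_feat_hr else
    as.matrix(d_feat_hr %*% interp_operator(in_dims, out_dims)$op)

  # ---- encoder backward ----
  bw <- conv_bw(cache$glob, par$enc$head, d_feat, in_dims, k)
  grads$enc$head$w <- bw$dw; grads$enc$head$b <- as.numeric(bw$db)
  d_glob <- bw$dx
  d_a_sh1 <- d_glob                       # global residual branch

  bw <- conv_bw(cache$gf1, par$enc$gfuse2, d_glob, in_dims, k)
  grads$enc$gfuse2$w <- bw$dw; grads$enc$gfuse2$b <- as.numeric(bw$db)
  bw <- conv_bw(cache$cat_g, par$enc$gfuse1, bw$dx, in_dims, 1L)
  grads$enc$gfuse1$w <- bw$dw; grads$enc$gfuse1$b <- as.numeric(bw$db)
  d_cat_g <- bw$dx

  carry <- NULL                           # gradient wrt RDB i's input
  for (i in seq(enc_cfg$n_rdb, 1L)) {
    rows <- ((i - 1L) * base + 1L):(i * base)
    d_g <- d_cat_g[rows, , drop = FALSE]
    if (!is.null(carry)) d_g <- d_g + carry
    rc <- cache$rdb[[i]]
    d_g0 <- d_g                           # local residual branch
    cat_full <- do.call(rbind, c(list(rc$g0), rc$cs))
    bw <- conv_bw(cat_full, par$enc$rdb[[i]]$fusion, d_g, in_dims, 1L)
    grads$enc$rdb[[i]]$fusion$w <- bw$dw
    grads$enc$rdb[[i]]$fusion$b <- as.numeric(bw$db)
    d_cat <- bw$dx
    d_g0 <- d_g0 + d_cat[seq_len(base), , drop = FALSE]
    d_cs <- lapply(seq_len(L), function(j)
      d_cat[(base + (j - 1L) * enc_cfg$growth_channels + 1L):
            (base + j * enc_cfg$growth_channels), , drop = FALSE])
    for (j in seq(L, 1L)) {
      dpre <- drelu_cpp(d_cs[[j]], rc$cs[[j]])
      inp <- do.call(rbind, c(list(rc$g0), rc$cs[seq_len(j - 1L)]))
      bw <- conv_bw(inp, par$enc$rdb[[i]]$conv[[j]], dpre, in_dims, k)
      grads$enc$rdb[[i]]$conv[[j]]$w <- bw$dw
      grads$enc$rdb[[i]]$conv[[j]]$b <- as.numeric(bw$db)
      d_g0 <- d_g0 + bw$dx[seq_len(base), , drop = FALSE]
      if (j > 1L) {
        for (jj in seq_len(j - 1L)) {
          rr <- (base + (jj - 1L) * enc_cfg$growth_channels + 1L):
                (base + jj * enc_cfg$growth_channels)
          d_cs[[jj]] <- d_cs[[jj]] + bw$dx[rr, , drop = FALSE]
        }
      }
    }
    carry <- d_g0
  }

  bw <- conv_bw(cache$a_sh1, par$enc$shallow2, carry, in_dims, k)
  grads$enc$shallow2$w <- bw$dw; grads$enc$shallow2$b <- as.numeric(bw$db)
  d_a_sh1 <- d_a_sh1 + bw$dx
  bw <- conv_bw(cache$x, par$enc$shallow1, d_a_sh1, in_dims, k)
  grads$enc$shallow1$w <- bw$dw; grads$enc$shallow1$b <- as.numeric(bw$db)

  list(total = ls$total, data_term = ls$data_term, reg_term = ls$reg_term,
       grads = grads, y_hat = y_hat)
}

# Rescale a gradient tree onto a global Euclidean-norm ball.
clip_gradients <- function(grads, clip_norm) {
  if (!is.finite(clip_norm)) return(grads)
  nrm <- sqrt(sum(rapply(grads, function(g) sum(g * g), how = "unlist")))
  if (nrm <= clip_norm) return(grads)
  sc <- clip_norm / nrm
  rapply(grads, function(g) g * sc, how = "replace")
}

# ---- Adam ----------------------------------------------------------------

adam_state <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_update <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  rec <- function(p, g, m, v) {
    if (is.numeric(p)) {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      p <- p - lr * (m / c1) / (sqrt(v / c2) + eps)
      return(list(p = p, m = m, v = v))
    }
    for (i in seq_along(p)) {
      r <- rec(p[[i]], g[[i]], m[[i]], v[[i]])
      p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
    }
    list(p = p, m = m, v = v)
  }
  r <- rec(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}
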