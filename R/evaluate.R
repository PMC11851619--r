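#' Simulate a phantom corpus
#'
#' Generates `n` high-resolution phantoms with seeds `seed + 0:(n-1)`,
#' cycling the four contrast profiles so each is equally represented
#' (mirroring a corpus stratified evenly over four acquisition sequences).
#'
#' @param n Number of phantoms.
#' @param grid_size Integer triple for every phantom.
#' @param seed Base seed; phantom `i` uses `seed + i - 1`.
#' @param profiles Contrast profiles to cycle through.
#' @param ... Further arguments to [phantom_spec()].
#' @return A list of `volume3d` objects carrying `volume_id` and `profile`
#'   attributes.
#' @export
simulate_corpus <- function(n, grid_size = c(32, 32, 32), seed = 1L,
                            profiles = c("react", "ncssfp", "ssfp", "irssfp"),
                            ...) {
  lapply(seq_len(n), function(i) {
    prof <- profiles[((i - 1L) %% length(profiles)) + 1L]
    vol <- generate_phantom(phantom_spec(grid_size = grid_size,
                                         contrast_profile = prof,
                                         seed = seed + i - 1L, ...))
    attr(vol, "volume_id") <- sprintf("phantom_%03d", i)
    attr(vol, "profile") <- prof
    vol
  })
}

# Resolve a method entry (sr_model or function(lr, s, target_dims)) into a
# prediction on the ground-truth grid.
predict_method <- function(method, lr_vol, s, target_dims) {
  if (inherits(method, "sr_model"))
    super_resolve(lr_vol, s, method, target_dims = target_dims)
  else
    method(lr_vol, s, target_dims)
}

#' Evaluate methods over a corpus and factor grid
#'
#' For every (volume, factor, method) combination, degrades the volume,
#' reconstructs it with the method on the ground-truth grid, and records
#' PSNR, SSIM, MSE and RMSE — one row per measurement, the shape of the
#' study's comparison tables. The default factor grid is
#' `{2, 2.5, 3, 3.5, 4}`.
#'
#' @param methods Named list; each element is an `sr_model` or a function
#'   `function(lr, s, target_dims)` returning a `volume3d` (e.g.
#'   [nearest_baseline()]).
#' @param corpus List of normalized high-resolution `volume3d` objects
#'   (see [simulate_corpus()]).
#' @param factors Numeric vector of scale factors.
#' @param degrade_method Degradation kernel.
#' @return A `metric_report` data.frame with columns `volume_id`,
#'   `contrast_profile`, `scale_factor`, `method_name`, `psnr_db`, `ssim`,
#'   `mse`, `rmse`.
#' @export
evaluate_corpus <- function(methods, corpus, factors = c(2, 2.5, 3, 3.5, 4),
                            degrade_method = "trilinear") {
  if (length(corpus) == 0)
    stop(fdosr_error("corpus must be nonempty", "fdosr_spec_error"))
  if (is.null(names(methods)) || any(!nzchar(names(methods))))
    stop(fdosr_error("methods must be a named list", "fdosr_spec_error"))
  rows <- list()
  for (vi in seq_along(corpus)) {
    hr <- as_volume3d(corpus[[vi]])
    vid <- attr(corpus[[vi]], "volume_id")
    if (is.null(vid)) vid <- sprintf("volume_%03d", vi)
    prof <- attr(corpus[[vi]], "profile")
    if (is.null(prof)) prof <- NA_character_
    for (s in factors) {
      lr_vol <- degrade(hr, s, method = degrade_method)
      lr_vol$data <- pmin(pmax(lr_vol$data, 0), 1)
      for (mn in names(methods)) {
        pred <- predict_method(methods[[mn]], lr_vol, s, dim(hr))
        m <- mse(pred, hr)
        rows[[length(rows) + 1L]] <- data.frame(
          volume_id = vid, contrast_profile = prof, scale_factor = s,
          method_name = mn, psnr_db = psnr(pred, hr),
          ssim = ssim3d(pred, hr), mse = m, rmse = sqrt(m),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("metric_report", "data.frame")
  out
}

#' Aggregate a metric report
#'
#' Mean and standard deviation of each metric per grouping (method by
#' factor by default; add `"contrast_profile"` for per-sequence rows).
#' Infinite PSNR sentinels (identical volumes) are excluded from PSNR
#' means.
#'
#' @param report A `metric_report`.
#' @param by Character vector of grouping columns.
#' @return A data.frame with `*_mean` and `*_sd` columns per metric.
#' @export
aggregate_report <- function(report, by = c("method_name", "scale_factor")) {
  groups <- interaction(report[by], drop = TRUE, lex.order = TRUE)
  agg <- function(v, finite_only = FALSE) {
    vapply(split(v, groups), function(x) {
      if (finite_only) x <- x[is.finite(x)]
      if (length(x) == 0) NA_real_ else mean(x)
    }, numeric(1))
  }
  sdv <- function(v, finite_only = FALSE) {
    vapply(split(v, groups), function(x) {
      if (finite_only) x <- x[is.finite(x)]
      if (length(x) < 2) NA_real_ else stats::sd(x)
    }, numeric(1))
  }
  keys <- do.call(rbind, lapply(split(report[by], groups), function(d) d[1, , drop = FALSE]))
  out <- cbind(keys,
               data.frame(psnr_mean = agg(report$psnr_db, TRUE),
                          psnr_sd = sdv(report$psnr_db, TRUE),
                          ssim_mean = agg(report$ssim), ssim_sd = sdv(report$ssim),
                          mse_mean = agg(report$mse), mse_sd = sdv(report$mse),
                          rmse_mean = agg(report$rmse), rmse_sd = sdv(report$rmse)))
  rownames(out) <- NULL
  out[order(out[[by[1]]]), , drop = FALSE]
}

#' Render an aggregated report as a Markdown table
#'
#' One section per metric, methods as columns and scale factors as rows —
#' the layout of a method-comparison table.
#'
#' @param report A `metric_report`.
#' @param digits Significant digits.
#' @return A character scalar of Markdown.
#' @export
report_markdown <- function(report, digits = 4) {
  agg <- aggregate_report(report)
  methods <- sort(unique(agg$method_name))
  factors <- sort(unique(agg$scale_factor))
  out <- character(0)
  for (metric in c("psnr_mean", "ssim_mean", "mse_mean", "rmse_mean")) {
    label <- toupper(sub("_mean", "", metric))
    out <- c(out, sprintf("**%s**", label), "",
             paste0("| Factor | ", paste(methods, collapse = " | "), " |"),
             paste0("|", paste(rep("---", length(methods) + 1), collapse = "|"), "|"))
    for (f in factors) {
      vals <- vapply(methods, function(m) {
        v <- agg[agg$method_name == m & agg$scale_factor == f, metric]
        if (length(v) == 0 || is.na(v)) "-" else format(signif(v, digits))
      }, character(1))
      out <- c(out, paste0("| ", f, "X | ", paste(vals, collapse = " | "), " |"))
    }
    out <- c(out, "")
  }
  paste(out, collapse = "\n")
}

#' Mean masked high-band residual over a corpus
#'
#' The quantity the frequency regularization targets, measured on held-out
#' data: for each volume, the masked spectral residual between the
#' method's reconstruction and the ground truth, averaged over the corpus.
#'
#' @param method An `sr_model` or prediction function (see
#'   [evaluate_corpus()]).
#' @param corpus List of high-resolution `volume3d` objects.
#' @param s Scale factor.
#' @param fraction Outer zero fraction of the mask.
#' @param degrade_method Degradation kernel.
#' @return Mean [fd_residual()] across the corpus.
#' @export
masked_residual_corpus <- function(method, corpus, s, fraction = 0.3,
                                   degrade_method = "trilinear") {
  masks <- new.env(parent = emptyenv())
  vals <- vapply(corpus, function(hr) {
    hr <- as_volume3d(hr)
    key <- paste(dim(hr), collapse = "_")
    if (is.null(masks[[key]])) masks[[key]] <- build_mask(dim(hr), fraction)
    lr_vol <- degrade(hr, s, method = degrade_method)
    lr_vol$data <- pmin(pmax(lr_vol$data, 0), 1)
    pred <- predict_method(method, lr_vol, s, dim(hr))
    fd_residual(pred, hr, masks[[key]])
  }, numeric(1))
  mean(vals)
}

#' Regularization-weight ablation sweep
#'
#' Trains one model per regularization weight under identical seeds and
#' configuration, then evaluates each on the test corpus. A run that
#' diverges (as large weights can) is recorded as a `"diverged"` status
#' row rather than aborting the sweep. The default weight grid is the
#' study's `{1e-2, 1e-3, 1e-5, 1e-10, 1e-15}`.
#'
#' @param corpus Training corpus (normalized `volume3d` list).
#' @param test_corpus Held-out corpus for evaluation.
#' @param lambdas Nonnegative weights to sweep.
#' @param cfg Base [training_config()]; its `lambda_reg` is overridden.
#' @param encoder,decoder Architecture configurations.
#' @param factors Evaluation factor grid.
#' @return A data.frame: the metric-report rows per weight plus `lambda`
#'   and `status` columns (`"ok"` or `"diverged"`, the latter with NA
#'   metrics).
#' @export
ablation_lambda <- function(corpus, test_corpus,
                            lambdas = c(1e-2, 1e-3, 1e-5, 1e-10, 1e-15),
                            cfg = training_config(),
                            encoder = encoder_config(),
                            decoder = decoder_config(),
                            factors = c(2, 2.5, 3, 3.5, 4)) {
  if (any(lambdas < 0))
    stop(fdosr_error("lambdas must be >= 0", "fdosr_spec_error"))
  rows <- lapply(lambdas, function(lam) {
    cfg_i <- cfg
    cfg_i$lambda_reg <- lam
    fit <- tryCatch(train(corpus, cfg_i, encoder, decoder),
                    fdosr_divergence_error = function(e) e)
    if (inherits(fit, "fdosr_divergence_error")) {
      data.frame(volume_id = NA_character_, contrast_profile = NA_character_,
                 scale_factor = NA_real_, method_name = sprintf("lambda_%g", lam),
                 psnr_db = NA_real_, ssim = NA_real_, mse = NA_real_,
                 rmse = NA_real_, lambda = lam, status = "diverged",
                 stringsAsFactors = FALSE)
    } else {
      rep_i <- evaluate_corpus(stats::setNames(list(fit$model),
                                               sprintf("lambda_%g", lam)),
                               test_corpus, factors,
                               degrade_method = cfg$degrade_method)
      rep_i$lambda <- lam
      rep_i$status <- "ok"
      as.data.frame(rep_i)
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("metric_report", "data.frame")
  out
}
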