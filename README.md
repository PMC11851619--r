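# fdosr

Arbitrary-scale 3D super-resolution with frequency-domain regularization,
implemented as a self-contained R package. Given a low-resolution
real-valued volume (the motivating case is isotropic whole-heart MRI),
`fdosr` reconstructs a high-resolution volume at **any** real
magnification factor in [2, 4] with a single trained model.

## The problem and the model

Volumetric acquisitions trade resolution against scan time, and classical
upsampling (nearest-neighbor, trilinear) blurs exactly the fine structure
— thin vessels, shell edges — that matters. `fdosr` trains a network with
two halves:

- **Encoder**: a residual dense network on the low-resolution grid — two
  shallow 3³ convolutions, a stack of residual dense blocks (densely
  concatenated conv+ReLU layers with a 1×1×1 fusion and local residual),
  global feature fusion with a global residual, and a head convolution to
  a feature field. No pooling, no normalization, no skip connections.
- **Arbitrary-scale decoder**: the feature field is trilinearly resampled
  to the requested output grid and a per-voxel MLP with shared weights
  emits one intensity per voxel. Because the geometry lives in the
  resampling step, any scale factor — 2, 2.5, 3.37, 4 — uses the same
  weights.

Training minimizes `mean(|error|) + lambda * fd_residual(error)`, where
`fd_residual` is the mean magnitude of the error's 3D Fourier coefficients
under a mask that selects the high-frequency band (the central
`round(0.7 * N)` per-axis box of the unshifted spectrum, where fine detail
lives). The network is initialized to *be* trilinear interpolation, so
training starts from a sensible operator and refines it; see the methods
vignette (`vignettes/fdosr-methods.Rmd`) for why this matters at short
training budgets.

The package also ships a cardiac-like synthetic phantom generator (tubes,
shells, gradients, four contrast profiles), image-space and k-space
degradation, PSNR/SSIM/MSE/RMSE evaluation harnesses, a regularization
ablation, NIfTI I/O, a deterministic end-to-end pipeline, and a CLI
(`inst/cli/fdosr`).

## Worked example

A two-minute demonstration (4 training phantoms, 40 optimization steps):

```r
library(fdosr)
train_set <- simulate_corpus(4, grid_size = c(32, 32, 32), seed = 1)
heldout <- simulate_corpus(2, grid_size = c(32, 32, 32), seed = 2001)

enc <- encoder_config(n_rdb = 2, base_channels = 32, growth_channels = 8,
                      feature_dim = 32)
dec <- decoder_config(n_layers = 4, hidden_width = 32)
cfg <- training_config(epochs = 10, lr_initial = 3e-4, lr_step_epochs = 3,
                       lr_gamma = 0.5, seed = 101, max_steps = 40)
fit <- train(train_set, cfg, enc, dec)

round(head(fit$history$loss, 3), 4)
#> [1] 0.0538 0.0416 0.0332

hr <- heldout[[1]]
lr <- degrade(hr, 2.5)                      # 32^3 -> 12^3
lr$data <- pmin(pmax(lr$data, 0), 1)
sr <- super_resolve(lr, 2.5, fit$model, target_dims = dim(hr))
psnr(sr, hr)                                # 23.11 dB at a fractional factor
```

Evaluating against the interpolation baselines on the held-out phantoms:

```r
report <- evaluate_corpus(
  list(model = fit$model,
       nearest = function(lr, s, td) nearest_baseline(lr, s, td),
       trilinear = function(lr, s, td) trilinear_baseline(lr, s, td)),
  heldout, factors = c(2, 3))
aggregate_report(report)[, c("method_name", "scale_factor",
                             "psnr_mean", "ssim_mean")]
#>   method_name scale_factor psnr_mean ssim_mean
#> 1       model            2     25.63    0.7681
#> 2       model            3     23.25    0.6256
#> 3     nearest            2     25.65    0.7976
#> 4     nearest            3     22.25    0.6044
#> 5   trilinear            2     25.58    0.7662
#> 6   trilinear            3     23.23    0.6227
```

Forty steps is only a demonstration — the model starts at trilinear
quality by construction and has just begun to pull ahead of it. The full
desk-scale protocol (16 phantoms, 200 steps, annealed learning rate, run
by the acceptance script below) reaches, on 8 held-out phantoms:

| factor | model | nearest | trilinear |
|---|---|---|---|
| 2 | **26.61 dB** | 26.37 dB | 26.47 dB |
| 3 | **23.89 dB** | 22.74 dB | 23.83 dB |
| 4 | **22.78 dB** | 21.97 dB | 22.77 dB |

## Command line

```sh
fdosr simulate --out corpus/ --n 4 --size 32 --seed 1
fdosr degrade --in hr.nii.gz --out lr.nii.gz --factor 2.5
fdosr train --config cfg.yaml
fdosr sr --in lr.nii.gz --out sr.nii.gz --model model.rds --factor 2.5
fdosr evaluate --config cfg.yaml --model model.rds
fdosr ablate --config cfg.yaml --lambdas 1e-2,1e-3,1e-5
fdosr pipeline --config cfg.yaml
```

The executable lives at `system.file("cli", "fdosr", package = "fdosr")`.

## A note on the frequency penalty at desk scale

The penalty's mean-over-coefficients reduction keeps λ's balance
independent of volume size, which also means its gradient is a fraction
of a percent of the data term's at λ = 10⁻³. Over long trainings this
pressure measurably lowers the masked high-band residual; over 200-step
desk runs it sits below seed-to-seed noise, and the acceptance suite
reports that comparison honestly (it is the one expected failure in the
test suite). The methods vignette derives the magnitudes.
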