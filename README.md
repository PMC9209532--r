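# srfmri

Subject-specific super-resolution fMRI and functional-resolution analysis.

## The problem

BOLD fMRI is acquired fast and coarse (typically 64 × 64 in-plane at
TR ≈ 0.5 s), while static T2\*-weighted images of the same anatomy — which
share the EPI contrast mechanism — can be acquired at 128 × 128 or finer.
When two functionally distinct cortical sites sit next to each other (thumb
vs little-finger representations in the primary motor cortex), their
low-resolution activation maps blur into one another. **Functional
resolution** — the ability to tell adjacent responses apart — is
operationalised here as the between-task Dice coefficient of the two
extracted activation regions: lower is better.

`srfmri` is for imaging-methods researchers who want to study whether
single-image super-resolution can recover functional resolution, with every
stage testable on synthetic data:

* **`sr_model`** — a modified SRGAN: no upsampling block (frames are
  Lanczos-3 pre-upscaled, the generator refines residuals on the target
  grid), no batch normalisation, pixel-MSE content loss +
  `1e-3 ×` adversarial loss, 10-conv-layer discriminator, Adam
  (β₁ = 0.9, lr = 1e-4, patch 64, batch 2). Trained per subject on that
  subject's own structural slice pair (`train_subject_model()`), applied
  frame-by-frame (`superresolve_series()`). Convolution forward/backward
  passes are compiled (im2col + GEMM); training is bit-reproducible by seed.
* **`preprocess`** — discard 60 equilibration scans, per-voxel linear
  detrend, zero-phase Butterworth low-pass (0.1 Hz default), in-plane
  Gaussian smoothing (σ = 1.5 px, reflective boundary).
* **`activation`** — per-task reference = boxcar ⊛ canonical double-gamma
  HRF; per-pixel statistic `CC = (R_x·R_y)/(|R_x||R_y|)`; region =
  inclusive superlevel set at `threshold = maxCC − (maxCC − minCC)/4`;
  super-resolved pixel counts divided by 4 for comparability.
* **`evaluation`** — between-task Dice, median (IQR) summaries, exact
  Wilcoxon signed-rank test (DP convolution over signed midranks; ties
  handled exactly).
* **`phantom`** — a ground-truth-known synthetic subject: paired 128/64
  structural stacks, a 900-volume 64 × 64 functional series with two
  partially overlapping elliptical active regions, HRF-convolved block
  design, drift and noise, block-average downsampling.

## Worked example

```r
library(srfmri)

design <- default_design()                 # thumb/little blocks, 900 vol @ 0.5 s
spec   <- confusable_phantom_spec(seed = 1L)  # regions the LR grid cannot resolve
ph     <- make_functional_series(spec, design)

# raw low-resolution arm
raw <- run_arm(ph$series_lr, design, mask = ph$truth$analysis_mask_lr)
raw$thumb$region
#> <activation_region> task 'thumb', threshold 0.4913, 21 px (normalized 21.00)

# idealised super-resolution arm: substitute the known high-resolution series
clean_hr <- ph$truth$clean_series_hr
hr <- run_arm(ph$series_lr, design, mask = ph$truth$analysis_mask_lr,
              sr = function(s) {
                nt <- dim(clean_hr$data)[4]
                keep <- (nt - dim(s)[4] + 1L):nt
                functional_series(clean_hr$data[, , , keep, drop = FALSE],
                                  tr = clean_hr$tr, pixel_size = clean_hr$pixel_size)
              })

dice(raw$thumb$region, raw$little$region)
#> <dice_result> 0.2609  (|A|=21, |B|=25, overlap=6)
dice(hr$thumb$region, hr$little$region)
#> <dice_result> 0.0000  (|A|=240, |B|=236, overlap=0)
```

The raw arm's thumb and little-finger regions overlap (Dice 0.26) because
partial-volume averaging and smoothing merge the two small responses on the
64 × 64 grid; analysing the high-resolution series separates them
(Dice 0). Across a cohort this is the package's headline comparison:

```r
study <- run_phantom_study(n_subjects = 10L, spec = confusable_phantom_spec(),
                           design = design, sr_mode = "truth_hr")
study$comparison
#> Paired arm comparison: raw vs truth_hr (Wilcoxon signed-rank, two-sided)
#>   dice_between_tasks     raw 0.338 (0.209-0.402) | truth_hr 0.000 (0.000-0.000) | p = 0.003906
#>   pixels_thumb           raw 22.500 (20.500-23.000) | truth_hr 60.000 (60.000-60.000) | p = 0.001953
#>   pixels_little          raw 21.500 (21.000-24.250) | truth_hr 59.000 (59.000-59.000) | p = 0.001953
```

The normalised pixel counts of the idealised high-resolution arm are
*larger* than the raw arm's: its noise-free CC map is nearly binary, so the
quarter-range threshold keeps a dilated version of the true regions. A real
super-resolution reconstruction carries the measurement noise through and
does not show this inflation; the Dice comparison is unaffected either way.

Training the actual SRGAN on a subject's structural pair:

```r
pair <- make_structural_pair(phantom_spec(seed = 1L, noise_sd = 0))
cfg  <- gan_config(iterations = 200L, n_resblocks = 4L, base_channels = 16L,
                   disc_base_channels = 16L, seed = 1L)
gen  <- train_subject_model(pair$hi, pair$lo, cfg)
psnr(pair$hi$data[, , 1], upscale_lanczos(pair$lo$data[, , 1], 2L))     # 24.00 dB
psnr(pair$hi$data[, , 1], superresolve_image(pair$lo$data[, , 1], gen)) # 24.25 dB
sr_series <- superresolve_series(ph$series_lr, gen)                   # 128 x 128 frames
```

A thin CLI (`inst/cli/srfmri.R`) exposes the same stages as
`simulate / preprocess / train / superres / analyze / evaluate / run-all`
subcommands over NIfTI + YAML files.

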