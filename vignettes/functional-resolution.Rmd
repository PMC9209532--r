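---
title: "Subject-specific super-resolution fMRI: model, phantom and evaluation methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subject-specific super-resolution fMRI: model, phantom and evaluation methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

BOLD fMRI trades spatial resolution for temporal resolution: a gradient-echo
EPI series is typically acquired on a 64 x 64 in-plane grid, while static
T2\*-weighted images (T2\*WI) of the same anatomy — which share the EPI
contrast mechanism, since both ride on T2\* relaxation — can be acquired at
128 x 128 or finer. When two functionally distinct cortical representations
sit next to each other (the thumb and little-finger areas of the primary
motor cortex are the canonical example), the low-resolution activation maps
of two different tapping tasks blur into each other. *Functional
resolution* is the ability to tell such adjacent responses apart; this
package operationalises it as the between-task Dice coefficient of the two
extracted activation regions — lower is better.

`srfmri` implements a subject-specific single-image super-resolution scheme
for this setting and everything needed to evaluate it end to end:

1. a super-resolution GAN trained, per subject, on that subject's own
   paired low/high-resolution static T2\*-like slices, then applied
   frame-by-frame to the functional series;
2. the activation-mapping chain (equilibrium-scan discarding, linear
   detrending, temporal low-pass, in-plane Gaussian smoothing,
   cross-correlation against an HRF-convolved task reference,
   range-threshold region extraction);
3. Dice-based separability analysis with an exact Wilcoxon signed-rank
   paired comparison;
4. a fully synthetic phantom with known ground truth, so all of the above
   is testable without any scanner data.

## The super-resolution model

The generator follows the SRGAN residual design with three deliberate
modifications:

* **No upsampling block.** Frames are upscaled to the target grid by
  Lanczos-3 interpolation *before* entering the network; the generator
  learns only the residual refinement. Its input and output therefore have
  the same spatial size, and an untrained (near-zero-initialised output
  convolution) generator is, by construction, almost exactly the Lanczos
  interpolator — a useful safety property: training starts from, and is
  measured against, the interpolation baseline.
* **No batch normalisation** in either network. BN layers couple inference
  to minibatch statistics and are known to introduce artifacts in
  super-resolution; with batch size 2 they would be ill-conditioned anyway.
* **Pixel-wise MSE content loss** (plus a small adversarial term), rather
  than a pretrained-network perceptual loss. A perceptual loss would drag
  in external trained weights, which is at odds with the subject-specific
  philosophy: nothing enters the model except this subject's own anatomy.

The discriminator has 10 convolutional 3 x 3 layers (stride 2 on every
second layer, channels doubling up to 8 x the base width), LeakyReLU(0.2)
activations, global average pooling and a dense layer producing the
real/fake logit. LeakyReLU(0.2) is used in the generator too: the usual
PReLU would add learned parameters for no observable benefit at these
widths.

Training hyperparameters (defaults of `gan_config()`): Adam with first-
moment decay 0.9, learning rate 1e-4, scale factor 2, patch size 64,
batch size 2, 100,000 iterations for a production run. Each iteration
samples aligned random 64 x 64 crops from the (Lanczos-upscaled low-res,
high-res) slice stacks; the discriminator is updated on real-vs-generated
crops with binary cross-entropy, then the generator on
`MSE + 1e-3 * BCE(D(fake), real)` (non-saturating). All randomness
(initialisation, crop sampling) derives from `gan_config(seed=)`, and
training is bit-reproducible for a fixed seed. A small set of held-out
random crops is tracked as validation loss every `val_interval` iterations.

Intensities are normalised to the low-resolution stack's robust 1st-99th
percentile range during training; the scaling is stored on the model and
reapplied at inference (`superresolve_series()`, `superresolve_image()`),
after `match_intensity()` has put the structural training data on the
functional series' intensity scale.

Everything is implemented from first principles — convolution forward and
backward passes in compiled code (im2col + GEMM), the training loop and
Adam in R — because the contribution under study *is* this network; there
is deliberately no dependency on an external deep-learning runtime.

Smoke-scale configurations used by the test-suite and the acceptance script
(16 feature channels, 4 residual blocks, 200 iterations at 64 -> 128) are
chosen so a training run completes in about a minute while still showing
the qualitative properties: decreasing content loss and PSNR at or above
the Lanczos baseline.

## Activation mapping

After discarding the first `n_discard = 60` volumes (magnetisation
equilibration at TR = 0.5 s), each voxel timecourse is linearly detrended
(ordinary least squares), low-pass filtered and each frame smoothed
in-plane. For each task, the reference timecourse is the task's on/off
boxcar sampled at the TR, convolved with the canonical double-gamma HRF
(response gamma with shape 6, undershoot gamma with shape 16, ratio 6 —
peak around 5 s), rescaled to peak 1 and truncated to the retained volumes.
The per-pixel statistic is the normalised dot product

    CC = (R_x . R_y) / (|R_x| |R_y|)

between the reference `R_x` and the voxel timecourse `R_y`. As printed this
is a cosine similarity; with the default `center = TRUE` both vectors are
mean-centred first, making it the Pearson correlation. After detrending the
two coincide to numerical precision, which is why the default is safe and
the flag is exposed.

The activation-related region is the *inclusive superlevel set* at the
range threshold

    threshold = maxCC - (maxCC - minCC) / 4

with the extrema taken over the supplied analysis mask (the "motor area";
whole-grid if no mask is given). The region always contains the in-mask
argmax, a constant map yields the whole mask, and adding a constant to the
map moves the threshold but not the region. Pixel counts from a 2x
super-resolved map are divided by 4 (`normalized_pixel_count()`) before
they are compared with native-grid counts.

Numerical choices:

* **Low-pass filter** — the filter family and cutoff are tunable because no
  single convention dominates; the default is a zero-phase (forward +
  backward) Butterworth of order 4 with a 0.1 Hz cutoff, conventional for a
  TR = 0.5 s block design. Zero phase matters because a causal filter would
  delay timecourses relative to the reference and bias CC downward. The
  implementation pads with odd reflection and uses steady-state initial
  conditions, so constants pass through exactly; it is vectorised across
  voxels.
* **Smoothing** — 2D in-plane only (the study design is slice-wise, and the
  SR model is 2D), Gaussian with sigma = 1.5 *pixels of the grid being
  smoothed*, truncated at 4 sigma, reflective boundaries, kernel rows
  renormalised so constants are fixed points and the global mean is
  preserved. On the super-resolved grid the same sigma covers half the
  physical extent — that asymmetry is intrinsic to resolution comparisons
  and is kept deliberately (an "unsmoothed" variant is available via
  `preprocess_config(smooth = FALSE)`).
* **Zero-variance timecourses** get CC = 0 and are counted on the map
  rather than producing NaNs.
* **Pipeline order** in `run_arm()` is discard -> super-resolve -> detrend
  -> low-pass -> smooth -> CC -> extract. Super-resolving before temporal
  preprocessing matches the scheme's layout (the generator sees frames that
  look like its training images, not detrended residuals); both arms share
  the same preprocessing, and the flags allow reproducing a rawer reading
  of the comparison arm.

## The phantom

`phantom_spec()` describes a single-slice functional phantom on a 128 x 128
high-resolution grid observed at 64 x 64: two elliptical active regions
(thumb / little finger surrogates) whose voxels carry
`baseline * (1 + amplitude * r(t))` with `r(t)` the task's HRF-convolved
boxcar (peak 1); overlap voxels respond to both tasks additively. Linear
drift and i.i.d. Gaussian noise are added at high resolution, then the
series is block-averaged (2 x 2 mean) to the low-resolution grid. Block
averaging — not Lanczos decimation — is the HR->LR operator because it is
the natural area-integrating acquisition model and is exactly testable (it
preserves the global per-frame mean, and the noise-free low-res series is
exactly the block average of the noise-free high-res series, which the
tests assert). The structural stack (30 slices, matching a typical
acquisition) is a smooth tissue-like pattern — elliptical "brain", bright
rim, random Gaussian blobs — with the low-res stack derived by block
averaging before each stack receives its own independent noise draw, as two
separate acquisitions would.

Parameter defaults and why:

* `n_volumes = 900`, `tr = 0.5` s, grids 128/64 — the acquisition regime
  the pipeline targets.
* `signal_amplitude = 0.03` (3% signal change) — a conventional motor-task
  BOLD effect size at 3 T.
* `noise_sd = 60` against `baseline = 700` — calibrated so that a single
  in-region low-resolution voxel reaches CC ~ 0.4-0.7 after detrending and
  low-pass filtering (median 0.61 measured at the defaults). This is the
  regime where the range threshold is neither trivial (CC ~ 1 everywhere in
  the region) nor hopeless.
* `overlap_fraction` — the fraction `|A ∩ B| / min(|A|, |B|)`; the centre
  separation is solved numerically (supersampled rasterisation + root
  finding) so the *rasterised* masks meet the requested fraction. Default
  0.15: adjacent, mildly overlapping representations.
* The default task design uses 15 s blocks separated by 30 s rests
  (alternating thumb / little finger). The rest phases keep the two
  reference regressors only mildly anticorrelated (rho ~ -0.2). This
  matters more than it looks: a voxel responding to *both* tasks has
  `CC <= sqrt((1 + rho) / 2)` against either reference, so with strongly
  anticorrelated references (short rests) dual-responding voxels can never
  enter both top-quartile regions and the between-task Dice degenerates to
  zero in every arm.

### The confusable variant

A separate constructor, `confusable_phantom_spec()`, produces the study
condition for the functional-resolution comparison: small regions
(semi-axes 4 x 6 high-res pixels — about 2 x 3 low-res pixels), strong
mask overlap (0.65) and a higher noise level (90). An analytic observation
drives this choice: for noise-free two-component responses, the region
extracted at the quarter-range threshold can be shown never to include
balanced mixture voxels (the mixture cosine `sqrt((1+rho)/2)` always falls
below the relative threshold `(3+rho)/4`), so low-resolution maps can only
overlap when partial-volume averaging plus smoothing erase the "pure"
voxels of each region *and* the noise floor pulls the in-mask minimum — and
with it the threshold — down. That requires regions comparable in size to
the low-resolution blur. Under this geometry the low-resolution arm's
regions overlap for most simulated subjects, while analysing the known
high-resolution series keeps them separable — the premise of the
super-resolution comparison, now testable: across 10 simulated subjects the
high-resolution arm's between-task Dice is never larger, and the paired
exact Wilcoxon test is significant.

### What the phantom does not emulate

No k-space or T2\* decay physics, no motion, no physiological (cardiac /
respiratory) noise, no spatial noise correlations, no susceptibility
distortion, and binary (not graded) response fields. Consequently, passing
tests show the *pipeline logic* is correct and that the resolution
mechanism behaves as designed under ideal partial-volume conditions; they
do not certify performance on scanner data. Two observed departures from
real-data behaviour are worth naming. First, the idealised
"ground-truth-HR substitution" arm analyses a noise-free series whose CC
map is nearly binary, so its extracted regions are *dilated* relative to
the true masks and its normalised pixel counts come out larger than the raw
arm's — the opposite of what a real SR reconstruction (which carries the
noise through) shows for pixel counts. The Dice comparison is unaffected.
Second, real cohorts include subjects where the comparison inverts for
data-quality reasons (training-image artifacts, task non-compliance);
the phantom has no such failure modes.

## Evaluation

Between-task Dice is computed on each arm's native grid — Dice is
scale-free, so no resampling is needed (a 2x upsampled pair of masks has
exactly the same Dice). The Wilcoxon signed-rank test is implemented in the
package: zero differences dropped, midranks for ties, exact null
distribution for n <= 25 computed by dynamic-programming convolution over
the signed ranks (so ties are handled exactly, without the no-ties
assumption of the classical tables), and a tie-corrected normal
approximation with continuity correction above. Tests cross-check it
against full 2^n enumeration and against `stats::wilcox.test` where
conventions coincide. Summaries are median (IQR) with linear-interpolation
(type 7) quantiles. Two-sided tests throughout; 0.05 is echoed in reports
but gates nothing.

## Problem sizes in the tests and acceptance script

The test-suite runs phantoms at full temporal length (900 volumes) but
mostly on reduced grids, and the GAN at 16 channels / 4 residual blocks /
200 iterations (about a minute of training); the cohort study uses 10
simulated subjects. These sizes were chosen to make the whole suite
comfortably rerunnable on a laptop while leaving every qualitative property
intact; production analyses would use `gan_config()` defaults.

## Known limitations

* The GAN is 2D and single-channel; no 3D extension is attempted.
* Training on CPU in R is adequate for the phantom scale but not for
  100,000-iteration production runs; the architecture is deliberately
  narrow there.
* The raw-vs-SR comparison inherits all caveats of the range threshold: it
  is relative to the in-mask extrema, so mask choice influences both arms.
* Coregistration/atlas handling is out of scope; the analysis mask is an
  input.
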