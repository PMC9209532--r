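#' Phantom specification
#'
#' Parameters of the synthetic finger-tapping phantom: a high-resolution
#' grid (default 128 x 128) carrying two partially overlapping elliptical
#' active regions (standing in for the adjacent thumb / little-finger
#' representations in the primary motor cortex), observed as a
#' block-averaged low-resolution series (default 64 x 64) of 900 volumes at
#' TR = 0.5 s. Activation follows an HRF-convolved block design at
#' `signal_amplitude` fractional signal change over baseline, with linear
#' scanner drift and i.i.d. Gaussian noise added at high resolution before
#' downsampling.
#'
#' @param grid_hr high-resolution matrix side in pixels (default 128).
#' @param scale integer downsampling factor; `grid_hr` must be divisible by
#'   it (default 2, giving a 64 x 64 low-resolution grid).
#' @param n_volumes functional volumes (default 900).
#' @param tr repetition time in seconds (default 0.5).
#' @param region_a,region_b ellipse descriptors: lists with `semi_x`,
#'   `semi_y` (high-res pixels) and `center_y_offset` (pixels from grid
#'   centre row).
#' @param overlap_fraction target `|A
#' intersect B| / min(|A|, |B|)` in `[0, 1)`; the centre separation along x
#'   is solved so the rasterised masks meet it (default 0.15).
#' @param signal_amplitude fractional BOLD signal change at the response
#'   peak (default 0.03, i.e. 3%).
#' @param baseline baseline tissue intensity (arbitrary MR units, default 700).
#' @param noise_sd high-resolution Gaussian noise s.d., intensity units
#'   (default 60; calibrated so single-voxel low-resolution CC after
#'   preprocessing falls around 0.4-0.7).
#' @param drift_slope linear drift in intensity units per volume
#'   (default 0.02).
#' @param n_slices_structural slices in the structural stack (default 30).
#' @param seed RNG seed for all stochastic elements.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_hr = 128L, scale = 2L, n_volumes = 900L,
                         tr = 0.5,
                         region_a = list(semi_x = 9, semi_y = 12,
                                         center_y_offset = 0),
                         region_b = list(semi_x = 9, semi_y = 12,
                                         center_y_offset = 0),
                         overlap_fraction = 0.15,
                         signal_amplitude = 0.03, baseline = 700,
                         noise_sd = 60, drift_slope = 0.02,
                         n_slices_structural = 30L, seed = 1L) {
  if (scale < 1L || grid_hr %% scale != 0L)
    stop("`grid_hr` must be a positive multiple of `scale`")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("`overlap_fraction` must be in [0, 1)")
  if (n_volumes < 1L) stop("`n_volumes` must be >= 1")
  if (noise_sd < 0 || signal_amplitude < 0) stop("negative noise/amplitude")
  for (r in list(region_a, region_b))
    if (r$semi_x <= 0 || r$semi_y <= 0) stop("ellipse semi-axes must be > 0")
  structure(list(grid_hr = as.integer(grid_hr), scale = as.integer(scale),
                 n_volumes = as.integer(n_volumes), tr = tr,
                 region_a = region_a, region_b = region_b,
                 overlap_fraction = overlap_fraction,
                 signal_amplitude = signal_amplitude, baseline = baseline,
                 noise_sd = noise_sd, drift_slope = drift_slope,
                 n_slices_structural = as.integer(n_slices_structural),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Phantom variant with low-resolution-confusable regions
#'
#' A [phantom_spec] whose two active regions are small relative to the
#' low-resolution blur (partial-volume averaging plus the 1.5-pixel
#' smoothing) and strongly overlapping, so the extracted low-resolution
#' activation regions overlap while the high-resolution ground truth keeps
#' them separable. This is the regime where super-resolution can improve
#' functional resolution, and the study condition for the between-task Dice
#' comparison; the plain [phantom_spec()] defaults instead give cleanly
#' recoverable, mildly overlapping regions.
#'
#' @param ... overrides passed to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
confusable_phantom_spec <- function(...) {
  args <- list(region_a = list(semi_x = 4, semi_y = 6, center_y_offset = 0),
               region_b = list(semi_x = 4, semi_y = 6, center_y_offset = 0),
               overlap_fraction = 0.65, noise_sd = 90)
  override <- list(...)
  args[names(override)] <- override
  do.call(phantom_spec, args)
}

# rasterise an ellipse; supersample > 1 returns the fractional coverage used
# by the overlap solver
ellipse_mask <- function(n, cx, cy, sx, sy, supersample = 1L) {
  m <- n * supersample
  xs <- (seq_len(m) - 0.5) / supersample
  outer((xs - cx) / sx, (xs - cy) / sy, function(a, b) a^2 + b^2) <= 1
}

# overlap fraction |A^B|/min(|A|,|B|) of the two ellipses at centre
# separation d along x, measured on a supersampled raster (smooth enough for
# root finding)
overlap_at_separation <- function(spec, d, supersample = 4L) {
  n <- spec$grid_hr
  c0 <- n / 2
  a <- spec$region_a; b <- spec$region_b
  ma <- ellipse_mask(n, c0 - d / 2, c0 + a$center_y_offset, a$semi_x, a$semi_y,
                     supersample)
  mb <- ellipse_mask(n, c0 + d / 2, c0 + b$center_y_offset, b$semi_x, b$semi_y,
                     supersample)
  sum(ma & mb) / min(sum(ma), sum(mb))
}

# centre separation (HR pixels, along x) achieving spec$overlap_fraction
solve_separation <- function(spec) {
  hi <- 2 * (spec$region_a$semi_x + spec$region_b$semi_x)
  if (spec$overlap_fraction == 0) return(hi)
  f <- function(d) overlap_at_separation(spec, d) - spec$overlap_fraction
  uniroot(f, lower = 0.5, upper = hi - 0.5, tol = 1e-3)$root
}

# the two ground-truth HR masks plus centres
phantom_masks_hr <- function(spec) {
  d <- solve_separation(spec)
  n <- spec$grid_hr
  c0 <- n / 2
  a <- spec$region_a; b <- spec$region_b
  ca <- c(c0 - d / 2, c0 + a$center_y_offset)
  cb <- c(c0 + d / 2, c0 + b$center_y_offset)
  list(mask_a = ellipse_mask(n, ca[1], ca[2], a$semi_x, a$semi_y),
       mask_b = ellipse_mask(n, cb[1], cb[2], b$semi_x, b$semi_y),
       center_a = ca, center_b = cb, separation = d)
}

#' Block-average downsampling
#'
#' Averages each non-overlapping `scale x scale` in-plane block; the exact
#' inverse relationship makes the high-to-low-resolution mapping testable
#' (it preserves the per-frame global mean exactly).
#'
#' @param x matrix or 3D/4D array whose first two dims are the image plane.
#' @param scale integer block edge.
#' @return The downsampled object of the same dimensionality.
#' @export
block_average <- function(x, scale = 2L) {
  d <- dim(x)
  if (d[1] %% scale != 0L || d[2] %% scale != 0L)
    stop("image side not divisible by `scale`")
  nx <- d[1] %/% scale; ny <- d[2] %/% scale
  rest <- if (length(d) > 2) prod(d[-(1:2)]) else 1L
  m <- array(x, dim = c(scale, nx, scale, ny * rest))
  m <- colMeans(m)                       # over first block dim -> (nx, scale, ny*rest)
  m <- array(aperm(m, c(2, 1, 3)), dim = c(scale, nx * ny * rest))
  out <- array(colMeans(m), dim = c(nx, ny, if (length(d) > 2) d[-(1:2)] else NULL))
  out
}

# smooth tissue-like HR slice: bright elliptical "brain" with random blobs
# and a rim, values roughly in [0, baseline*1.4]
structural_slice_hr <- function(spec, n_blobs = 8L) {
  n <- spec$grid_hr
  xs <- seq_len(n) - 0.5
  c0 <- n / 2
  rx <- 0.42 * n; ry <- 0.46 * n
  rr <- outer(((xs - c0) / rx)^2, ((xs - c0) / ry)^2, `+`)
  brain <- rr <= 1
  img <- matrix(0, n, n)
  img[brain] <- spec$baseline
  rim <- rr <= 1 & rr >= 0.88
  img[rim] <- spec$baseline * 1.35
  for (i in seq_len(n_blobs)) {
    bc <- runif(2, 0.25 * n, 0.75 * n)
    bs <- runif(1, 0.03 * n, 0.1 * n)
    amp <- runif(1, -0.3, 0.35) * spec$baseline
    img <- img + brain * amp * exp(-outer((xs - bc[1])^2, (xs - bc[2])^2, `+`) /
                                     (2 * bs^2))
  }
  pmax(img, 0)
}

#' Generate the paired structural slice stacks
#'
#' Produces the subject's static structural training pair: a stack of
#' smooth, tissue-like high-resolution slices (sum of an elliptical brain,
#' a bright rim and random Gaussian blobs) and its low-resolution
#' counterpart. The low-resolution stack is the exact block average of the
#' noise-free high-resolution stack; with `noise_sd > 0` each stack then
#' receives its own independent Gaussian noise draw, as two separate
#' acquisitions would.
#'
#' @param spec a [phantom_spec].
#' @return List with `hi` and `lo` ([structural_image]s at pixel sizes 1 and
#'   `scale`).
#' @export
make_structural_pair <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    n <- spec$grid_hr
    ns <- spec$n_slices_structural
    hi <- array(0, dim = c(n, n, ns))
    for (s in seq_len(ns)) hi[, , s] <- structural_slice_hr(spec)
    lo <- array(0, dim = c(n %/% spec$scale, n %/% spec$scale, ns))
    for (s in seq_len(ns)) lo[, , s] <- block_average(hi[, , s], spec$scale)
    if (spec$noise_sd > 0) {
      hi <- hi + rnorm(length(hi), 0, spec$noise_sd)
      lo <- lo + rnorm(length(lo), 0, spec$noise_sd)
    }
    list(hi = structural_image(hi, pixel_size = 1),
         lo = structural_image(lo, pixel_size = spec$scale))
  })
}

#' Default two-task block design for the phantom
#'
#' Alternating task blocks with resting phases between them
#' (rest, task A, rest, task B, ...), repeated while a full task block still
#' fits in the run. Rest phases longer than the task blocks keep the two
#' task regressors only mildly anticorrelated, as in slow event-related
#' somatotopy designs.
#'
#' @param n_volumes,tr series length and repetition time.
#' @param block_s task block duration in seconds (default 15).
#' @param rest_s resting phase between blocks in seconds (default 30).
#' @param labels the two task labels.
#' @return A [task_design].
#' @export
default_design <- function(n_volumes = 900L, tr = 0.5, block_s = 15,
                           rest_s = 30, labels = c("thumb", "little")) {
  total <- n_volumes * tr
  onsets <- seq(rest_s, total - block_s, by = block_s + rest_s)
  task <- rep(labels, length.out = length(onsets))
  task_design(data.frame(task = task, onset = onsets, duration = block_s),
              tr = tr, n_volumes = n_volumes)
}

#' Generate the low-resolution functional series with ground truth
#'
#' Builds the noise-free high-resolution series
#' `baseline_map * (1 + amplitude * (mask_A * r_A(t) + mask_B * r_B(t)))`
#' where `r_A`, `r_B` are the tasks' HRF-convolved boxcars (peak 1); voxels
#' in the overlap carry both responses. Linear drift and i.i.d. Gaussian
#' noise are then added at high resolution and the result block-averaged to
#' the low-resolution grid.
#'
#' @param spec a [phantom_spec].
#' @param design a [task_design] with exactly two task labels and matching
#'   `n_volumes`/`tr`; default [default_design()] under the spec's timing.
#' @return List with:
#'   * `series_lr` — the noisy low-resolution [functional_series];
#'   * `truth` — ground truth: `mask_a_hr`, `mask_b_hr`, the corresponding
#'     majority-vote LR masks, `analysis_mask_lr`/`_hr` (a dilated hull
#'     around both regions, the phantom's "motor area"), `clean_series_hr`
#'     (noise- and drift-free), `series_lr_clean`, centres, and the
#'     downsampling operator description.
#' @export
make_functional_series <- function(spec, design = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(design)) design <- default_design(spec$n_volumes, spec$tr)
  if (design$n_volumes != spec$n_volumes || design$tr != spec$tr)
    stop("design length/TR does not match the phantom spec")
  labs <- task_labels(design)
  if (length(labs) != 2L) stop("phantom design needs exactly two task labels")
  mk <- phantom_masks_hr(spec)
  n <- spec$grid_hr; nt <- spec$n_volumes
  ra <- build_reference(design, labs[1])$values
  rb <- build_reference(design, labs[2])$values
  base_hr <- with_seed(spec$seed + 1L, structural_slice_hr(spec, n_blobs = 4L))
  base_hr <- pmax(base_hr, 0.15 * spec$baseline)  # avoid zero-signal voxels
  npx <- n * n
  bvec <- as.vector(base_hr)
  act <- outer(as.vector(mk$mask_a) * spec$signal_amplitude, ra) +
    outer(as.vector(mk$mask_b) * spec$signal_amplitude, rb)
  clean <- bvec * (1 + act)                      # (npx, nt)
  series_hr <- clean +
    matrix(spec$drift_slope * (seq_len(nt) - 1L), npx, nt, byrow = TRUE)
  if (spec$noise_sd > 0)
    series_hr <- series_hr +
      with_seed(spec$seed + 2L,
                matrix(rnorm(npx * nt, 0, spec$noise_sd), npx, nt))
  dim(series_hr) <- c(n, n, 1L, nt)
  dim(clean) <- c(n, n, 1L, nt)
  lr <- block_average(series_hr, spec$scale)
  lr_clean <- block_average(clean, spec$scale)
  # analysis mask: dilated hull around both regions (the known "motor area")
  hull <- smooth_spatial(
    matrix(as.numeric(mk$mask_a | mk$mask_b), n, n), sigma = 4) > 0.02
  amask_hr <- array(hull, dim = c(n, n, 1L))
  amask_lr <- array(block_average(matrix(as.numeric(hull), n, n),
                                  spec$scale) > 0, dim = dim(lr)[1:3])
  to_lr_mask <- function(m)
    array(block_average(matrix(as.numeric(m), n, n), spec$scale) >= 0.5,
          dim = dim(lr)[1:3])
  truth <- list(
    mask_a_hr = array(mk$mask_a, dim = c(n, n, 1L)),
    mask_b_hr = array(mk$mask_b, dim = c(n, n, 1L)),
    mask_a_lr = to_lr_mask(mk$mask_a),
    mask_b_lr = to_lr_mask(mk$mask_b),
    analysis_mask_hr = amask_hr, analysis_mask_lr = amask_lr,
    clean_series_hr = functional_series(clean, tr = spec$tr, pixel_size = 1),
    series_lr_clean = functional_series(lr_clean, tr = spec$tr,
                                        pixel_size = spec$scale),
    center_a = mk$center_a, center_b = mk$center_b,
    separation_hr = mk$separation, task_labels = labs,
    downsample_operator = sprintf("block_average_%d", spec$scale))
  list(series_lr = functional_series(lr, tr = spec$tr,
                                     pixel_size = spec$scale),
       truth = truth)
}
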