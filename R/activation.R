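#' Canonical double-gamma hemodynamic response function
#'
#' The conventional canonical HRF: a gamma density peaking near 5 s minus a
#' later gamma undershoot (peak parameter 16) scaled by `1/ratio`. Evaluated
#' at times `t` (seconds).
#'
#' @param t times in seconds.
#' @param peak shape of the response gamma (unit rate), default 6.
#' @param undershoot shape of the undershoot gamma, default 16.
#' @param ratio response-to-undershoot amplitude ratio, default 6.
#' @return Numeric vector of HRF values (unnormalised).
#' @export
hrf_double_gamma <- function(t, peak = 6, undershoot = 16, ratio = 6) {
  dgamma(t, shape = peak, rate = 1) -
    dgamma(t, shape = undershoot, rate = 1) / ratio
}

# 0/1 boxcar for one task label, sampled at frame times (i-1)*tr
task_boxcar <- function(design, task_label) {
  b <- design$blocks[design$blocks$task == task_label, , drop = FALSE]
  if (nrow(b) == 0L) stop(sprintf("unknown task label '%s'", task_label))
  tt <- (seq_len(design$n_volumes) - 1L) * design$tr
  box <- numeric(design$n_volumes)
  for (i in seq_len(nrow(b)))
    box[tt >= b$onset[i] - 1e-9 & tt < b$onset[i] + b$duration[i] - 1e-9] <- 1
  box
}

#' Build the HRF-convolved task reference timecourse
#'
#' Constructs the reference regressor for one task: an on/off boxcar (1
#' during that task's blocks) sampled at the TR, convolved with the
#' canonical double-gamma HRF, rescaled to peak 1, with the first
#' `n_discard` samples dropped so it aligns with a series whose equilibrium
#' scans were discarded.
#'
#' @param design a [task_design].
#' @param task_label one of the design's task labels.
#' @param n_discard number of leading volumes dropped from the series.
#' @param hrf `"double_gamma"` (default) or `"impulse"` (no convolution;
#'   mainly for verification).
#' @return An object of class `reference_timecourse` with fields `values`
#'   and `task_label`.
#' @export
build_reference <- function(design, task_label, n_discard = 0L,
                            hrf = c("double_gamma", "impulse")) {
  hrf <- match.arg(hrf)
  box <- task_boxcar(design, task_label)
  if (hrf == "double_gamma") {
    tk <- seq(0, 32, by = design$tr)
    kern <- hrf_double_gamma(tk)
    v <- convolve(box, rev(kern), type = "open")[seq_along(box)]
  } else {
    v <- box
  }
  if (n_discard >= length(v)) stop("discard count leaves no samples")
  v <- v[(n_discard + 1L):length(v)]
  if (all(abs(v) < 1e-12))
    stop(sprintf("task '%s' has no activity after discarding", task_label))
  v <- v / max(abs(v))
  structure(list(values = v, task_label = task_label),
            class = "reference_timecourse")
}

#' Cross-correlation activation map
#'
#' For every in-mask pixel, the normalised dot product between the reference
#' timecourse R_x and the pixel timecourse R_y:
#' `CC = (R_x . R_y) / (|R_x| |R_y|)`.
#' With `center = TRUE` (default) both vectors are mean-centred first, making
#' CC the Pearson correlation; without centring it is the raw cosine
#' similarity (the two coincide after detrending, which zeroes the means).
#' Pixels with zero temporal variance get CC = 0 and are counted in the
#' `n_zero_variance` attribute.
#'
#' @param series a preprocessed [functional_series].
#' @param ref a `reference_timecourse` from [build_reference()] whose length
#'   equals the series' time dimension.
#' @param mask logical array on the series' spatial grid (`x, y, slice`), or
#'   `NULL` for all pixels.
#' @param center mean-centre before correlating? (default `TRUE`)
#' @return A `cc_map`: list with `values` (3D array, `NA` outside the mask),
#'   `mask`, `task_label`.
#' @export
cc_map <- function(series, ref, mask = NULL, center = TRUE) {
  stopifnot(inherits(series, "functional_series"),
            inherits(ref, "reference_timecourse"))
  nt <- n_volumes(series)
  if (length(ref$values) != nt)
    stop(sprintf("reference length %d != series length %d",
                 length(ref$values), nt))
  d <- dim(series$data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dim = d)
  if (!identical(dim(mask), d)) stop("mask grid does not match series grid")
  if (!any(mask)) stop("mask is empty")
  m <- series_as_matrix(series)[as.vector(mask), , drop = FALSE]
  r <- ref$values
  if (center) {
    r <- r - mean(r)
    m <- m - rowMeans(m)
  }
  nr <- sqrt(sum(r^2))
  nm <- sqrt(rowSums(m^2))
  cc <- as.vector(m %*% r)
  zero <- nm < 1e-12 * max(nm, 1)
  cc[!zero] <- cc[!zero] / (nr * nm[!zero])
  cc[zero] <- 0
  vals <- array(NA_real_, dim = d)
  vals[mask] <- cc
  structure(list(values = vals, mask = mask, task_label = ref$task_label,
                 n_zero_variance = sum(zero)),
            class = "cc_map")
}

#' @export
print.cc_map <- function(x, ...) {
  cat(sprintf("<cc_map> task '%s', %d in-mask pixels, CC range [%.3f, %.3f]\n",
              x$task_label, sum(x$mask), min(x$values, na.rm = TRUE),
              max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Range threshold for activation-region extraction
#'
#' The threshold sits a quarter of the CC range below the maximum:
#' `threshold = maxCC - (maxCC - minCC) / 4`, i.e. the top 25% of the
#' observed CC range counts as activation-related.
#'
#' @param max_cc,min_cc in-mask CC extrema.
#' @return The threshold value.
#' @export
range_threshold <- function(max_cc, min_cc) {
  if (min_cc > max_cc) stop("min_cc exceeds max_cc")
  max_cc - (max_cc - min_cc) / 4
}

#' Extract the activation-related region from a CC map
#'
#' The region is the inclusive superlevel set of the in-mask CC values at
#' the [range_threshold()]: every in-mask pixel with `CC >= threshold`. It
#' always contains the in-mask maximum; on a constant map the threshold
#' equals that constant and the region is the whole mask.
#'
#' @param ccmap a `cc_map`.
#' @param resolution_factor area ratio of one analysis pixel between grids
#'   (4 when the map is on a 2x super-resolved grid); stored on the result
#'   and used by [normalized_pixel_count()].
#' @return An `activation_region`: list with `mask` (logical array),
#'   `threshold_used`, `raw_pixel_count`, `normalized_count`, `task_label`.
#' @export
extract_region <- function(ccmap, resolution_factor = 1) {
  stopifnot(inherits(ccmap, "cc_map"))
  vals <- ccmap$values[ccmap$mask]
  if (length(vals) == 0L) stop("empty analysis mask")
  thr <- range_threshold(max(vals), min(vals))
  region <- ccmap$mask & !is.na(ccmap$values) & ccmap$values >= thr
  reg <- structure(
    list(mask = region, threshold_used = thr,
         raw_pixel_count = sum(region),
         normalized_count = sum(region) / resolution_factor,
         resolution_factor = resolution_factor,
         task_label = ccmap$task_label),
    class = "activation_region")
  reg
}

#' @export
print.activation_region <- function(x, ...) {
  cat(sprintf(
    "<activation_region> task '%s', threshold %.4f, %d px (normalized %.2f)\n",
    x$task_label, x$threshold_used, x$raw_pixel_count, x$normalized_count))
  invisible(x)
}

#' Resolution-normalised pixel count
#'
#' Pixel counts measured on a super-resolved grid are divided by the pixel
#' area ratio (4 for a 2x upscale) so they are comparable with counts on the
#' native grid.
#'
#' @param region an `activation_region`.
#' @param resolution_factor area ratio (>= 1), e.g. 4 for 2x in-plane
#'   super-resolution, 1 for the native grid.
#' @return The normalised (possibly fractional) count.
#' @export
normalized_pixel_count <- function(region, resolution_factor = 1) {
  stopifnot(inherits(region, "activation_region"))
  if (resolution_factor < 1) stop("`resolution_factor` must be >= 1")
  region$raw_pixel_count / resolution_factor
}

# nearest-neighbour 2x-ish upsample of a logical/numeric mask (x, y, slice)
upsample_mask_nn <- function(mask, scale) {
  d <- dim(mask)
  out <- mask[rep(seq_len(d[1]), each = scale),
              rep(seq_len(d[2]), each = scale), , drop = FALSE]
  out
}

#' Run one analysis arm end to end
#'
#' Executes the per-arm pipeline on a low-resolution series:
#' discard equilibrium scans, optionally super-resolve every remaining frame
#' (the "STSS" arm), then detrend, low-pass, smooth, and compute one CC map
#' and activation region per task. In the super-resolved arm the analysis
#' mask is nearest-neighbour-upsampled to the high-resolution grid and the
#' region's `normalized_count` uses `resolution_factor = scale^2`.
#'
#' @param series_lr the low-resolution [functional_series].
#' @param design a [task_design] matching the *un-discarded* series.
#' @param mask logical analysis mask on the low-resolution grid (or `NULL`).
#' @param sr how to super-resolve: `NULL` (raw arm), a `trained_generator`,
#'   the string `"lanczos"` (interpolation only), or a function
#'   `function(series) -> series` (e.g. substituting a known high-resolution
#'   series in simulation studies).
#' @param config a [preprocess_config].
#' @param center passed to [cc_map()].
#' @return List with one element per task label, each holding `cc` (the
#'   `cc_map`) and `region` (the `activation_region`), plus attributes
#'   `arm` and `scale`.
#' @export
run_arm <- function(series_lr, design, mask = NULL, sr = NULL,
                    config = preprocess_config(), center = TRUE) {
  stopifnot(inherits(series_lr, "functional_series"),
            inherits(design, "task_design"))
  series <- discard_initial(series_lr, config$n_discard)
  scale <- 1L
  arm <- "raw"
  if (!is.null(sr)) {
    if (inherits(sr, "trained_generator")) {
      scale <- sr$config$scale
      series <- superresolve_series(series, sr)
      arm <- "stss"
    } else if (is.function(sr)) {
      old <- dim(series$data)[1]
      series <- sr(series)
      scale <- dim(series$data)[1] %/% old
      arm <- "substituted"
    } else if (identical(sr, "lanczos")) {
      scale <- 2L
      series <- lanczos_series(series, scale)
      arm <- "lanczos"
    } else stop("`sr` must be NULL, a trained_generator, a function, or \"lanczos\"")
  }
  if (isTRUE(config$detrend)) series <- detrend_linear(series)
  if (isTRUE(config$lowpass))
    series <- lowpass_temporal(series, config$lowpass_cutoff)
  if (isTRUE(config$smooth)) series <- smooth_spatial(series, config$spatial_sigma)
  if (!is.null(mask) && scale > 1L) mask <- upsample_mask_nn(mask, scale)
  res <- lapply(task_labels(design), function(lab) {
    ref <- build_reference(design, lab, n_discard = config$n_discard)
    cc <- cc_map(series, ref, mask = mask, center = center)
    list(cc = cc, region = extract_region(cc, resolution_factor = scale^2))
  })
  names(res) <- task_labels(design)
  attr(res, "arm") <- arm
  attr(res, "scale") <- scale
  res
}
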