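#' Preprocessing configuration
#'
#' Bundles the temporal/spatial preprocessing chain applied before
#' activation mapping: discard the first `n_discard` equilibrium scans,
#' remove a per-voxel linear trend, low-pass filter each voxel timecourse
#' (zero-phase Butterworth, order 4) and smooth each frame in-plane with a
#' Gaussian kernel.
#'
#' @param n_discard number of initial volumes to drop (default 60, the
#'   conventional equilibration allowance at TR = 0.5 s).
#' @param detrend remove per-voxel linear trends? (default `TRUE`)
#' @param lowpass apply the temporal low-pass filter? (default `TRUE`)
#' @param lowpass_cutoff temporal cutoff in Hz (default 0.1; must stay below
#'   the Nyquist frequency `1/(2 TR)`).
#' @param smooth apply in-plane Gaussian smoothing? (default `TRUE`)
#' @param spatial_sigma Gaussian sigma in pixels of the grid being smoothed
#'   (default 1.5).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(n_discard = 60L, detrend = TRUE,
                              lowpass = TRUE, lowpass_cutoff = 0.1,
                              smooth = TRUE, spatial_sigma = 1.5) {
  if (n_discard < 0) stop("`n_discard` must be >= 0")
  if (spatial_sigma < 0) stop("`spatial_sigma` must be >= 0")
  if (lowpass_cutoff <= 0) stop("`lowpass_cutoff` must be positive")
  structure(list(n_discard = as.integer(n_discard), detrend = detrend,
                 lowpass = lowpass, lowpass_cutoff = lowpass_cutoff,
                 smooth = smooth, spatial_sigma = spatial_sigma),
            class = "preprocess_config")
}

# series data as (voxel x time) matrix and back; the 4D layout already has
# time last, so both directions are copy-free reshapes
series_as_matrix <- function(series) {
  d <- dim(series$data)
  m <- series$data
  dim(m) <- c(prod(d[1:3]), d[4])
  m
}

matrix_as_series <- function(m, template) {
  d <- dim(template$data)
  d[4] <- ncol(m)
  dim(m) <- d
  functional_series(m, tr = template$tr, pixel_size = template$pixel_size,
                    slice_thickness = template$slice_thickness)
}

#' Discard initial (equilibrium) volumes
#'
#' Drops the first `n` frames of the series, the scans acquired before the
#' longitudinal magnetisation reaches steady state; remaining frames are
#' untouched.
#'
#' @param series a [functional_series].
#' @param n number of leading volumes to drop; must be `< n_volumes`.
#' @return The shortened [functional_series].
#' @export
discard_initial <- function(series, n = 60L) {
  stopifnot(inherits(series, "functional_series"))
  nt <- n_volumes(series)
  if (n >= nt) stop(sprintf("cannot discard %d of %d volumes", n, nt))
  if (n == 0L) return(series)
  functional_series(series$data[, , , (n + 1L):nt, drop = FALSE],
                    tr = series$tr, pixel_size = series$pixel_size,
                    slice_thickness = series$slice_thickness)
}

#' Remove per-voxel linear trends
#'
#' Fits and subtracts an ordinary least-squares line (intercept + slope)
#' from every voxel timecourse; output timecourses have zero mean and zero
#' fitted slope. Scanner drift over a long run is well approximated by this
#' linear component.
#'
#' @param series a [functional_series] with at least 3 time points.
#' @return The detrended [functional_series].
#' @export
detrend_linear <- function(series) {
  stopifnot(inherits(series, "functional_series"))
  nt <- n_volumes(series)
  if (nt < 3L) stop("need at least 3 time points to detrend")
  m <- series_as_matrix(series)
  x <- cbind(1, seq_len(nt) - (nt + 1) / 2)   # centred time: orthogonal design
  coef <- (m %*% x) %*% solve(crossprod(x))   # (voxel x 2)
  matrix_as_series(m - tcrossprod(coef, x), series)
}

# Butterworth zero-phase filtering of a (voxel x time) matrix: odd-reflected
# end padding plus a forward and a backward pass (the filtfilt construction),
# vectorised over voxels in compiled code.
filtfilt_matrix <- function(m, b, a) iir_filtfilt(m, b, a)

#' Temporal low-pass filter
#'
#' Attenuates each voxel timecourse above `cutoff` with a zero-phase
#' (forward-backward) Butterworth filter of the given order. Zero phase
#' matters here: the activation analysis correlates timecourses against a
#' task reference, so the filter must not delay the signal. The DC component
#' (voxel mean) is preserved.
#'
#' @param series a [functional_series].
#' @param cutoff cutoff frequency in Hz; must be below Nyquist `1/(2 TR)`.
#' @param order Butterworth order of each pass (default 4).
#' @return The filtered [functional_series].
#' @export
lowpass_temporal <- function(series, cutoff = 0.1, order = 4L) {
  stopifnot(inherits(series, "functional_series"))
  nyq <- 1 / (2 * series$tr)
  if (cutoff >= nyq)
    stop(sprintf("cutoff %g Hz is not below Nyquist %g Hz", cutoff, nyq))
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  m <- filtfilt_matrix(series_as_matrix(series), bf$b, bf$a)
  matrix_as_series(m, series)
}

# 1D Gaussian smoothing operator on n points: reflective (symmetric)
# boundary, kernel truncated at 4 sigma, rows renormalised to sum 1 so
# constants are fixed points. Returned as an n x n matrix applied by GEMM.
gaussian_smoother_matrix <- function(n, sigma) {
  if (sigma == 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma))
  w <- exp(-(-r:r)^2 / (2 * sigma^2))
  K <- matrix(0, n, n)
  for (off in -r:r) {
    idx <- seq_len(n) + off
    # whole-sample symmetric reflection: ... 3 2 1 | 1 2 3 ... n | n n-1 ...
    idx <- ifelse(idx < 1L, 1L - idx, idx)
    idx <- ifelse(idx > n, 2L * n + 1L - idx, idx)
    K[cbind(seq_len(n), idx)] <- K[cbind(seq_len(n), idx)] + w[off + r + 1L]
  }
  K / rowSums(K)
}

smooth_frame <- function(frame, Kx, Ky) Kx %*% frame %*% t(Ky)

#' In-plane Gaussian spatial smoothing
#'
#' Convolves every 2D frame (each slice, each time point) with a normalised
#' Gaussian kernel of standard deviation `sigma` pixels, truncated at 4
#' sigma, with reflective boundary handling. `sigma = 0` is the identity.
#' Sigma is interpreted in pixels of the grid being smoothed, so the same
#' numeric value smooths a high-resolution map over a proportionally smaller
#' physical extent.
#'
#' @param x a [functional_series], [structural_image], 2D matrix, or a
#'   `cc_map`.
#' @param sigma Gaussian standard deviation in pixels (>= 0).
#' @return The same type as `x`, smoothed.
#' @export
smooth_spatial <- function(x, sigma = 1.5) {
  if (sigma < 0) stop("`sigma` must be >= 0")
  if (sigma == 0) return(x)
  if (is.matrix(x)) {
    Kx <- gaussian_smoother_matrix(nrow(x), sigma)
    Ky <- gaussian_smoother_matrix(ncol(x), sigma)
    return(smooth_frame(x, Kx, Ky))
  }
  if (inherits(x, "functional_series")) {
    d <- dim(x$data)
    Kx <- gaussian_smoother_matrix(d[1], sigma)
    Ky <- gaussian_smoother_matrix(d[2], sigma)
    out <- array(0, dim = d)
    for (s in seq_len(d[3])) {
      # batch all frames of the slice into two GEMMs (one per image axis)
      a <- matrix(x$data[, , s, ], d[1], d[2] * d[4])
      a <- array(Kx %*% a, dim = c(d[1], d[2], d[4]))
      a <- matrix(aperm(a, c(2, 1, 3)), d[2], d[1] * d[4])
      out[, , s, ] <- aperm(array(Ky %*% a, dim = c(d[2], d[1], d[4])),
                            c(2, 1, 3))
    }
    return(functional_series(out, tr = x$tr, pixel_size = x$pixel_size,
                             slice_thickness = x$slice_thickness))
  }
  if (inherits(x, "structural_image")) {
    d <- dim(x$data)
    Kx <- gaussian_smoother_matrix(d[1], sigma)
    Ky <- gaussian_smoother_matrix(d[2], sigma)
    out <- x$data
    for (s in seq_len(d[3])) out[, , s] <- smooth_frame(x$data[, , s], Kx, Ky)
    return(structural_image(out, pixel_size = x$pixel_size,
                            slice_thickness = x$slice_thickness))
  }
  stop("unsupported input type for smoothing")
}

#' Apply the full preprocessing chain
#'
#' Runs discard -> detrend -> low-pass -> smooth in that order, honouring
#' the flags in `config`.
#'
#' @param series a [functional_series].
#' @param config a [preprocess_config].
#' @return The preprocessed [functional_series].
#' @export
preprocess_series <- function(series, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  out <- discard_initial(series, config$n_discard)
  if (isTRUE(config$detrend)) out <- detrend_linear(out)
  if (isTRUE(config$lowpass)) out <- lowpass_temporal(out, config$lowpass_cutoff)
  if (isTRUE(config$smooth)) out <- smooth_spatial(out, config$spatial_sigma)
  out
}
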