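test_that("discard_initial drops exactly the leading frames", {
  s <- random_series(nt = 120)
  out <- discard_initial(s, 60L)
  expect_equal(dim(out)[4], 60L)
  expect_identical(out$data, s$data[, , , 61:120, drop = FALSE])
  expect_identical(discard_initial(s, 0L)$data, s$data)
  expect_error(discard_initial(s, 120L), "cannot discard")
})

test_that("detrend_linear removes lines exactly and matches an explicit LS solve", {
  nt <- 50L
  tt <- seq_len(nt)
  # exact line -> all zeros
  line <- functional_series(array(rep(3 + 0.25 * tt, each = 4),
                                  c(2, 2, 1, nt)), tr = 1)
  expect_lt(max(abs(detrend_linear(line)$data)), 1e-10)
  # constant -> all zeros
  const <- functional_series(array(7, c(2, 2, 1, nt)), tr = 1)
  expect_lt(max(abs(detrend_linear(const)$data)), 1e-12)
  # random series: residuals match an independent normal-equations solve,
  # and output has zero mean and zero fitted slope
  set.seed(11)
  s <- random_series(nx = 3, ny = 3, nt = nt, seed = 11)
  out <- detrend_linear(s)
  for (i in 1:3) for (j in 1:3) {
    y <- s$data[i, j, 1, ]
    expect_equal(out$data[i, j, 1, ], unname(residuals(lm(y ~ tt))),
                 tolerance = 1e-10)
  }
  m <- apply(out$data, 4, mean)
  expect_lt(abs(mean(out$data)), 1e-10)
  fit <- coef(lm(as.vector(out$data[1, 1, 1, ]) ~ tt))[2]
  expect_lt(abs(fit), 1e-10)
  # idempotence
  expect_equal(detrend_linear(out)$data, out$data, tolerance = 1e-10)
})

test_that("temporal low-pass preserves DC and passband, attenuates stopband", {
  nt <- 400L; tr <- 0.5
  tt <- (seq_len(nt) - 1) * tr
  mk <- function(v) functional_series(array(v, c(1, 1, 1, nt)), tr = tr)
  # constant timecourse is a fixed point
  out <- lowpass_temporal(mk(rep(5, nt)), 0.1)
  expect_equal(as.vector(out$data), rep(5, nt), tolerance = 1e-8)
  # amplitude measured by projection onto the generating sinusoid
  amp <- function(v, f) {
    b <- cbind(sin(2 * pi * f * tt), cos(2 * pi * f * tt))
    sqrt(sum((2 / nt) * crossprod(b, v)^2))
  }
  hi <- sin(2 * pi * 0.8 * tt)   # well above 0.1 Hz cutoff
  out_hi <- as.vector(lowpass_temporal(mk(hi), 0.1)$data)
  expect_lt(amp(out_hi, 0.8), amp(hi, 0.8) / 10)
  lo <- sin(2 * pi * 0.02 * tt)  # well below cutoff
  out_lo <- as.vector(lowpass_temporal(mk(lo), 0.1)$data)
  expect_equal(amp(out_lo, 0.02), amp(lo, 0.02), tolerance = 0.05)
  # cutoff must stay below Nyquist
  expect_error(lowpass_temporal(mk(hi), 1.0), "Nyquist")
})

test_that("zero-phase filtering matches signal::filtfilt on a single voxel", {
  set.seed(5)
  v <- rnorm(300)
  bf <- signal::butter(4, 0.2, type = "low")
  ours <- as.vector(srfmri:::filtfilt_matrix(matrix(v, 1), bf$b, bf$a))
  ref <- signal::filtfilt(bf, v)
  # the two constructions differ in end-padding details, so compare away
  # from the edges
  expect_lt(max(abs(ours[30:270] - ref[30:270])), 1e-3)
  expect_gt(cor(ours[30:270], ref[30:270]), 0.9999)
})

test_that("spatial smoothing: identity at sigma 0, kernel normalisation, impulse response", {
  img <- matrix(rnorm(32 * 32), 32)
  expect_identical(smooth_spatial(img, 0), img)
  # constant image is a fixed point
  cimg <- matrix(3.7, 24, 24)
  expect_equal(smooth_spatial(cimg, 1.5), cimg, tolerance = 1e-12)
  # single-pixel impulse reproduces the closed-form Gaussian centre value
  imp <- matrix(0, 33, 33); imp[17, 17] <- 1
  sm <- smooth_spatial(imp, 1.5)
  expect_equal(sm[17, 17], 1 / (2 * pi * 1.5^2), tolerance = 1e-3)
  # global mean preserved (reflective boundary), within 1e-6 relative
  set.seed(2)
  r <- matrix(runif(40 * 40, 10, 20), 40)
  expect_equal(mean(smooth_spatial(r, 1.5)), mean(r), tolerance = 1e-6)
  expect_error(smooth_spatial(img, -1), "sigma")
})

test_that("the full chain runs in order and reduces to its parts", {
  s <- random_series(nx = 8, ny = 8, nt = 140, seed = 3)
  cfg <- preprocess_config(n_discard = 20L, lowpass_cutoff = 0.1,
                           spatial_sigma = 1)
  out <- preprocess_series(s, cfg)
  expect_equal(dim(out)[4], 120L)
  manual <- smooth_spatial(
    lowpass_temporal(detrend_linear(discard_initial(s, 20L)), 0.1), 1)
  expect_equal(out$data, manual$data, tolerance = 1e-12)
  # smoothing off reproduces the unsmoothed variant
  cfg2 <- preprocess_config(n_discard = 20L, smooth = FALSE)
  expect_equal(preprocess_series(s, cfg2)$data,
               lowpass_temporal(detrend_linear(discard_initial(s, 20L)),
                                0.1)$data,
               tolerance = 1e-12)
})
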