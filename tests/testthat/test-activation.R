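test_that("canonical HRF peaks 5-6 s after a brief stimulus", {
  tt <- seq(0, 32, by = 0.1)
  h <- hrf_double_gamma(tt)
  expect_gte(tt[which.max(h)], 5)
  expect_lte(tt[which.max(h)], 6)
  # undershoot present and small relative to the peak
  expect_lt(min(h), 0)
  expect_lt(abs(min(h)) / max(h), 0.3)
})

test_that("build_reference: boxcar identity with impulse kernel, errors on bad labels", {
  d <- task_design(data.frame(task = c("a", "b"), onset = c(20, 50),
                              duration = c(10, 10)), tr = 0.5,
                   n_volumes = 160)
  ref <- build_reference(d, "a", n_discard = 0L, hrf = "impulse")
  box <- srfmri:::task_boxcar(d, "a")
  expect_equal(ref$values, box / max(box))
  expect_error(build_reference(d, "missing"), "unknown task")
  # discarding everything up to after the only block empties the boxcar
  d2 <- task_design(data.frame(task = "a", onset = 2, duration = 3),
                    tr = 0.5, n_volumes = 160)
  expect_error(build_reference(d2, "a", n_discard = 60L, hrf = "impulse"),
               "no activity")
})

test_that("cc_map reproduces the normalised dot product exactly", {
  d <- dim3 <- c(2, 5, 1)
  nt <- 20L
  set.seed(8)
  arr <- array(rnorm(prod(dim3) * nt), c(dim3, nt))
  s <- functional_series(arr, tr = 1)
  rv <- rnorm(nt)
  ref <- structure(list(values = rv, task_label = "x"),
                   class = "reference_timecourse")
  m <- cc_map(s, ref, center = TRUE)
  # brute-force element-by-element oracle
  for (i in 1:2) for (j in 1:5) {
    y <- arr[i, j, 1, ] - mean(arr[i, j, 1, ])
    r <- rv - mean(rv)
    expect_equal(m$values[i, j, 1], sum(r * y) / sqrt(sum(r^2) * sum(y^2)),
                 tolerance = 1e-12)
  }
  # identical / negated / orthogonal timecourses
  a2 <- array(0, c(1, 3, 1, nt))
  a2[1, 1, 1, ] <- rv
  a2[1, 2, 1, ] <- -rv
  rc <- rv - mean(rv)
  orth <- rnorm(nt)
  orth <- orth - mean(orth)
  orth <- orth - rc * sum(orth * rc) / sum(rc^2)
  a2[1, 3, 1, ] <- orth
  m2 <- cc_map(functional_series(a2, tr = 1), ref)
  expect_equal(m2$values[1, 1, 1], 1, tolerance = 1e-12)
  expect_equal(m2$values[1, 2, 1], -1, tolerance = 1e-12)
  expect_equal(m2$values[1, 3, 1], 0, tolerance = 1e-12)
  # zero-variance pixel flagged and set to 0
  a3 <- array(1, c(1, 1, 1, nt))
  m3 <- cc_map(functional_series(a3, tr = 1), ref)
  expect_equal(m3$values[1, 1, 1], 0)
  expect_equal(m3$n_zero_variance, 1L)
  # length mismatch rejected
  expect_error(cc_map(functional_series(array(1, c(1, 1, 1, 5)), tr = 1), ref),
               "length")
})

test_that("CC values are bounded by 1 in magnitude over random inputs", {
  set.seed(13)
  for (rep in 1:10) {
    s <- random_series(nx = 6, ny = 6, nt = 15, seed = rep)
    rv <- rnorm(15)
    ref <- structure(list(values = rv, task_label = "x"),
                     class = "reference_timecourse")
    m <- cc_map(s, ref)
    expect_lte(max(abs(m$values)), 1 + 1e-12)
  }
})

test_that("range threshold arithmetic and region extraction", {
  expect_equal(range_threshold(1.0, 0.0), 0.75)
  expect_equal(range_threshold(0.8, 0.4), 0.7)
  expect_error(range_threshold(0.2, 0.5), "exceeds")
  # constant map: threshold equals the constant, region is the whole mask
  cm <- cc_map_from_values(matrix(0.42, 5, 5))
  reg <- extract_region(cm)
  expect_equal(reg$threshold_used, 0.42)
  expect_true(all(reg$mask))
  # region is exactly the inclusive superlevel set, and contains the argmax
  set.seed(17)
  for (rep in 1:20) {
    vals <- matrix(runif(64, -1, 1), 8)
    mask <- array(runif(64) < 0.7, c(8, 8, 1))
    if (!any(mask)) next
    cm <- cc_map_from_values(vals, mask)
    reg <- extract_region(cm)
    inmask <- vals[mask[, , 1]]
    thr <- max(inmask) - (max(inmask) - min(inmask)) / 4
    expected <- mask & array(vals >= thr, c(8, 8, 1))
    expect_identical(reg$mask, expected)
    expect_true(reg$mask[which.max(ifelse(mask, vals, -Inf))])
    # translation equivariance: +c shifts the threshold, not the region
    reg2 <- extract_region(cc_map_from_values(vals + 0.3, mask))
    expect_identical(reg2$mask, reg$mask)
    expect_equal(reg2$threshold_used, reg$threshold_used + 0.3)
  }
})

test_that("pixel-count normalisation matches the grid-area ratio", {
  set.seed(23)
  m <- matrix(runif(100) < 0.5, 10)
  cm <- cc_map_from_values(ifelse(m, 1, 0))
  reg <- extract_region(cm, resolution_factor = 1)
  expect_equal(normalized_pixel_count(reg, 4), sum(m & TRUE) / 4)
  expect_equal(normalized_pixel_count(reg, 1), reg$raw_pixel_count)
  # exact 2x nearest-neighbour upsample quadruples the count exactly
  up <- upsample2_nn(m)
  cmu <- cc_map_from_values(ifelse(up, 1, 0))
  regu <- extract_region(cmu, resolution_factor = 4)
  expect_equal(regu$normalized_count, sum(m))
  expect_error(normalized_pixel_count(reg, 0.5), ">= 1")
})

test_that("substituting an interpolation-only upscaler equals analysing upscaled frames", {
  spec <- tiny_spec(noise_sd = 10)
  design <- tiny_design()
  ph <- make_functional_series(spec, design)
  cfg <- preprocess_config(n_discard = 20L)
  lr_mask <- ph$truth$analysis_mask_lr
  arm_sub <- run_arm(ph$series_lr, design, mask = lr_mask,
                     sr = function(s) srfmri:::lanczos_series(s, 2L),
                     config = cfg)
  up_series <- srfmri:::lanczos_series(ph$series_lr, 2L)
  hr_mask <- srfmri:::upsample_mask_nn(lr_mask, 2L)
  arm_up <- run_arm(up_series, design, mask = hr_mask, sr = NULL, config = cfg)
  for (lab in names(arm_sub)) {
    expect_equal(arm_sub[[lab]]$cc$values, arm_up[[lab]]$cc$values,
                 tolerance = 1e-10)
    expect_identical(arm_sub[[lab]]$region$mask, arm_up[[lab]]$region$mask)
  }
  # normalisation differs: the substituted arm knows it runs on a finer grid
  expect_equal(arm_sub[[1]]$region$normalized_count,
               arm_sub[[1]]$region$raw_pixel_count / 4)
  expect_equal(arm_up[[1]]$region$normalized_count,
               arm_up[[1]]$region$raw_pixel_count)
})

test_that("raw arm recovers the phantom's regions on a quiet phantom", {
  spec <- tiny_spec(noise_sd = 5)
  design <- tiny_design()
  ph <- make_functional_series(spec, design)
  res <- run_arm(ph$series_lr, design, mask = ph$truth$analysis_mask_lr,
                 config = preprocess_config(n_discard = 20L,
                                            spatial_sigma = 1))
  labs <- ph$truth$task_labels
  truth <- list(ph$truth$mask_a_lr, ph$truth$mask_b_lr)
  for (i in 1:2) {
    d <- dice(res[[labs[i]]]$region, truth[[i]])
    expect_gte(d$dice, 0.5)
  }
})
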