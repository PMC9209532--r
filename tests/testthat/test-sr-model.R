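test_that("Lanczos-3 upscaling: geometry, identity and flat-field behaviour", {
  img <- matrix(rnorm(64 * 64, 500, 50), 64)
  up <- upscale_lanczos(img, 2L)
  expect_equal(dim(up), c(128L, 128L))
  expect_equal(upscale_lanczos(img, 1L), img, tolerance = 1e-6)
  flat <- matrix(7, 16, 16)
  expect_equal(upscale_lanczos(flat, 2L), matrix(7, 32, 32),
               tolerance = 1e-12)
  expect_error(upscale_lanczos(img, 1.5), "integer")
})

test_that("intensity matching maps the robust range onto the reference", {
  s <- structural_image(array(runif(32 * 32 * 2), c(32, 32, 2)))
  ref <- functional_series(array(runif(16 * 16 * 1 * 4, 0, 1000),
                                 c(16, 16, 1, 4)), tr = 1)
  out <- match_intensity(s, ref)
  qs <- quantile(out$data, c(0.01, 0.99), names = FALSE)
  qr <- quantile(ref$data, c(0.01, 0.99), names = FALSE)
  expect_equal(qs, qr, tolerance = 1e-9)
  # monotone affine: ordering preserved
  expect_equal(order(s$data[1:50]), order(out$data[1:50]))
  const <- structural_image(array(5, c(8, 8, 1)))
  expect_error(match_intensity(const, ref), "constant")
})

test_that("psnr: cap for identical images, closed form for constant offset, brute force", {
  a <- matrix(runif(100), 10)
  expect_equal(psnr(a, a), 300)
  b <- a + 0.01
  a1 <- a; a1[1] <- 0; a1[2] <- 1   # force unit range
  expect_equal(psnr(a1, a1 + 0.01), 20 * log10(1 / 0.01), tolerance = 1e-9)
  set.seed(3)
  x <- matrix(rnorm(64), 8); y <- matrix(rnorm(64), 8)
  expect_equal(psnr(x, y),
               10 * log10(diff(range(x))^2 / mean((x - y)^2)),
               tolerance = 1e-12)
  expect_error(psnr(a, matrix(0, 5, 5)), "shape")
})

test_that("convolution gradients match numerical differentiation", {
  set.seed(41)
  for (stride in c(1L, 2L)) {
    x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
    p <- srfmri:::conv_init(3, 2, 3)
    out <- srfmri:::conv_fw(x, p, stride, 1L)
    g <- array(rnorm(length(out)), dim(out))
    bw <- srfmri:::conv_bw(x, p, g, stride, 1L)
    eps <- 1e-6
    num_grad <- function(f, z) {
      vapply(seq_along(z), function(i) {
        z1 <- z; z2 <- z
        z1[i] <- z[i] + eps; z2[i] <- z[i] - eps
        (f(z1) - f(z2)) / (2 * eps)
      }, numeric(1))
    }
    gx_num <- num_grad(function(z)
      sum(srfmri:::nn_conv_fw(array(z, dim(x)), p$w, p$b, stride, 1L) * g),
      as.vector(x))
    gw_num <- num_grad(function(z)
      sum(srfmri:::nn_conv_fw(x, matrix(z, nrow(p$w)), p$b, stride, 1L) * g),
      as.vector(p$w))
    expect_lt(max(abs(gx_num - as.vector(bw$gx))), 1e-6)
    expect_lt(max(abs(gw_num - as.vector(bw$gw))), 1e-6)
    expect_equal(as.vector(bw$gb), apply(g, 3, sum), tolerance = 1e-9)
  }
})

test_that("generator and discriminator graphs have the required structure", {
  cfg <- gan_config(n_resblocks = 3L, base_channels = 8L,
                    disc_base_channels = 8L, iterations = 1L)
  gen <- untrained_generator(cfg)
  arch <- gen$architecture
  # no batch normalisation anywhere
  expect_false(any(grepl("batch|norm", arch$layer, ignore.case = TRUE)))
  # discriminator has exactly the configured number of conv layers (10)
  cfg10 <- gan_config(n_disc_conv = 10L, disc_base_channels = 8L)
  gen10 <- untrained_generator(cfg10)
  disc_layers <- gen10$architecture[
    gen10$architecture$component == "discriminator", "layer"]
  expect_equal(sum(grepl("^conv", disc_layers)), 10L)
  # generator preserves spatial size (pre-upscaled design)
  x <- matrix(rnorm(24 * 24), 24)
  y <- srfmri:::gen_forward(gen$params, x)
  expect_equal(dim(y)[1:2], c(24L, 24L))
})

test_that("untrained generator reproduces the Lanczos upscale almost exactly", {
  cfg <- gan_config(n_resblocks = 2L, base_channels = 8L,
                    disc_base_channels = 8L, seed = 9L)
  gen <- untrained_generator(cfg, scaling = c(0, 1))
  set.seed(10)
  s <- functional_series(array(runif(16 * 16 * 1 * 3), c(16, 16, 1, 3)),
                         tr = 0.5, pixel_size = 2)
  out <- superresolve_series(s, gen)
  expect_equal(dim(out$data), c(32L, 32L, 1L, 3L))
  expect_equal(out$pixel_size, 1)
  base <- srfmri:::lanczos_series(s, 2L)
  expect_lt(max(abs(out$data - base$data)), 0.05)
  # inference is deterministic
  out2 <- superresolve_series(s, gen)
  expect_identical(out$data, out2$data)
})

test_that("short adversarial training runs, descends and is seed-reproducible", {
  spec <- phantom_spec(grid_hr = 64L, n_slices_structural = 2L, seed = 8L,
                       noise_sd = 0)
  pair <- make_structural_pair(spec)
  cfg <- gan_config(iterations = 80L, patch_size = 32L, n_resblocks = 2L,
                    base_channels = 8L, disc_base_channels = 8L,
                    val_interval = 20L, seed = 123L)
  gen <- train_subject_model(pair$hi, pair$lo, cfg)
  expect_length(gen$loss_history, 80L)
  expect_true(all(is.finite(gen$loss_history)))
  # window-averaged content loss should not increase over this run
  expect_lte(mean(tail(gen$loss_history, 20)),
             mean(head(gen$loss_history, 20)) * 1.05)
  expect_lte(tail(gen$validation$val_loss, 1), gen$validation$val_loss[1])
  expect_equal(nrow(gen$validation), 4L)
  # bit-identical rerun under the same seed
  gen2 <- train_subject_model(pair$hi, pair$lo, cfg)
  expect_identical(gen$loss_history, gen2$loss_history)
  expect_identical(gen$params, gen2$params)
  # contract errors
  bad <- gan_config(patch_size = 256L)
  expect_error(train_subject_model(pair$hi, pair$lo, bad), "patch size")
  expect_error(train_subject_model(pair$lo, pair$lo, cfg), "times")
})

test_that("model checkpoints round-trip through a single archive", {
  cfg <- gan_config(n_resblocks = 1L, base_channels = 4L,
                    disc_base_channels = 4L)
  gen <- untrained_generator(cfg)
  path <- tempfile(fileext = ".rds")
  write_model(gen, path)
  gen2 <- read_model(path)
  expect_identical(gen2$params, gen$params)
  expect_identical(gen2$config, gen$config)
  unlink(path)
})
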