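#' GAN training configuration
#'
#' Hyperparameters of the modified SRGAN. The generator works on frames that
#' were already Lanczos-3-upscaled to the target grid (no upsampling block),
#' contains no batch normalisation, and is trained with a pixel-wise MSE
#' content loss plus a small adversarial term against a discriminator with
#' `n_disc_conv` convolutional layers.
#'
#' @param scale integer super-resolution factor (default 2).
#' @param patch_size training crop edge in high-res pixels (default 64).
#' @param batch_size crops per optimiser step (default 2).
#' @param lr Adam learning rate (default 1e-4).
#' @param adam_beta1 Adam first-moment decay rate (default 0.9).
#' @param adam_beta2 Adam second-moment decay rate (default 0.999).
#' @param iterations optimiser steps (default 100000; use a few hundred for
#'   smoke runs).
#' @param n_disc_conv discriminator convolutional layers (default 10).
#' @param n_resblocks generator residual blocks (default 16; 4 is plenty for
#'   small phantoms).
#' @param base_channels generator feature channels (default 64).
#' @param disc_base_channels discriminator base channels (default 64).
#' @param adv_weight weight of the adversarial term in the generator loss
#'   (default 1e-3).
#' @param content_loss only `"mse"` is implemented.
#' @param val_crops held-out random crops used to track validation loss
#'   (default 4).
#' @param val_interval iterations between validation evaluations (default 50).
#' @param seed RNG seed covering initialisation and patch sampling.
#' @return A `gan_config` list.
#' @export
gan_config <- function(scale = 2L, patch_size = 64L, batch_size = 2L,
                       lr = 1e-4, adam_beta1 = 0.9, adam_beta2 = 0.999,
                       iterations = 100000L, n_disc_conv = 10L,
                       n_resblocks = 16L, base_channels = 64L,
                       disc_base_channels = 64L, adv_weight = 1e-3,
                       content_loss = "mse", val_crops = 4L,
                       val_interval = 50L, seed = 1L) {
  if (scale < 1L) stop("`scale` must be >= 1")
  if (any(c(patch_size, batch_size, iterations, n_disc_conv, n_resblocks,
            base_channels) < 1L)) stop("all counts must be positive")
  if (content_loss != "mse") stop("only the pixel-MSE content loss is implemented")
  structure(list(scale = as.integer(scale), patch_size = as.integer(patch_size),
                 batch_size = as.integer(batch_size), lr = lr,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 iterations = as.integer(iterations),
                 n_disc_conv = as.integer(n_disc_conv),
                 n_resblocks = as.integer(n_resblocks),
                 base_channels = as.integer(base_channels),
                 disc_base_channels = as.integer(disc_base_channels),
                 adv_weight = adv_weight, content_loss = content_loss,
                 val_crops = as.integer(val_crops),
                 val_interval = as.integer(val_interval),
                 seed = as.integer(seed)),
            class = "gan_config")
}

lanczos_weight <- function(x, a = 3) {
  w <- numeric(length(x))
  small <- abs(x) < 1e-12
  w[small] <- 1
  inb <- !small & abs(x) < a
  xi <- x[inb]
  w[inb] <- a * sin(pi * xi) * sin(pi * xi / a) / (pi^2 * xi^2)
  w
}

# (n_in*scale) x n_in resampling operator; edge samples clamp, rows
# renormalised so constants are preserved
lanczos_matrix <- function(n_in, scale, a = 3) {
  n_out <- n_in * scale
  L <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    x <- (i - 0.5) / scale - 0.5          # 0-based source coordinate
    js <- (floor(x) - a + 1):(floor(x) + a)
    w <- lanczos_weight(x - js, a)
    js <- pmin(pmax(js, 0), n_in - 1)
    for (k in seq_along(js)) L[i, js[k] + 1L] <- L[i, js[k] + 1L] + w[k]
  }
  L / rowSums(L)
}

#' Lanczos-3 upscaling
#'
#' Separable Lanczos interpolation with kernel support `a = 3`, the
#' conventional high-quality resampler; this is the fixed front end of the
#' generator (the network refines the interpolated frame rather than
#' learning its own upsampling).
#'
#' @param image 2D matrix.
#' @param scale positive integer factor; `scale = 1` is the identity.
#' @return The upscaled matrix (`side * scale`).
#' @export
upscale_lanczos <- function(image, scale = 2L) {
  if (!is.matrix(image)) stop("`image` must be a matrix")
  if (length(scale) != 1L || scale < 1 || scale != round(scale))
    stop("`scale` must be a positive integer")
  if (scale == 1L) return(image)
  Lx <- lanczos_matrix(nrow(image), as.integer(scale))
  Ly <- lanczos_matrix(ncol(image), as.integer(scale))
  Lx %*% image %*% t(Ly)
}

# upscale every frame of a series (interpolation-only arm)
lanczos_series <- function(series, scale = 2L) {
  d <- dim(series$data)
  out <- array(0, dim = c(d[1] * scale, d[2] * scale, d[3], d[4]))
  Lx <- lanczos_matrix(d[1], scale)
  Ly <- lanczos_matrix(d[2], scale)
  for (s in seq_len(d[3])) for (t in seq_len(d[4]))
    out[, , s, t] <- Lx %*% series$data[, , s, t] %*% t(Ly)
  functional_series(out, tr = series$tr,
                    pixel_size = series$pixel_size / scale,
                    slice_thickness = series$slice_thickness)
}

#' Match structural intensities to a functional reference
#'
#' Applies the monotone affine map sending the structural image's robust
#' (1st/99th percentile) intensity range onto the reference series' range,
#' so the training images live on the same scale as the frames the model
#' will later see.
#'
#' @param structural a [structural_image].
#' @param reference a [functional_series].
#' @param probs the two percentiles defining the robust range.
#' @return The rescaled [structural_image].
#' @export
match_intensity <- function(structural, reference, probs = c(0.01, 0.99)) {
  stopifnot(inherits(structural, "structural_image"),
            inherits(reference, "functional_series"))
  qs <- quantile(structural$data, probs, names = FALSE)
  qr <- quantile(reference$data, probs, names = FALSE)
  if (diff(qs) < 1e-12 * max(abs(qs), 1))
    stop("structural image is (near-)constant; cannot match intensity")
  dat <- (structural$data - qs[1]) / diff(qs) * diff(qr) + qr[1]
  structural_image(dat, pixel_size = structural$pixel_size,
                   slice_thickness = structural$slice_thickness)
}

robust_range <- function(x, probs = c(0.01, 0.99))
  quantile(x, probs, names = FALSE)

normalize_frame <- function(x, rng) (x - rng[1]) / (rng[2] - rng[1])
denormalize_frame <- function(x, rng) x * (rng[2] - rng[1]) + rng[1]

#' Train the subject-specific super-resolution generator
#'
#' Adversarial training on one subject's structural slice pair. Each
#' iteration samples `batch_size` aligned random crops from the
#' (Lanczos-upscaled low-res, high-res) stacks, updates the discriminator on
#' real vs generated crops (binary cross-entropy), then updates the
#' generator on `MSE + adv_weight * BCE(D(fake), real)` (non-saturating).
#' Intensities are normalised to the low-res stack's robust range during
#' training; the scaling is stored on the model and reapplied at inference.
#'
#' @param hi high-resolution [structural_image] (side = low side x scale).
#' @param lo low-resolution [structural_image], same slice count.
#' @param config a [gan_config].
#' @return A `trained_generator`: generator parameters, the config, per-
#'   iteration content/adversarial/discriminator loss histories, validation
#'   loss table, the intensity scaling used, and an architecture table.
#' @export
train_subject_model <- function(hi, lo, config = gan_config()) {
  stopifnot(inherits(hi, "structural_image"), inherits(lo, "structural_image"),
            inherits(config, "gan_config"))
  dh <- dim(hi$data); dl <- dim(lo$data)
  if (dh[3] != dl[3]) stop("slice counts differ")
  if (dh[1] != dl[1] * config$scale || dh[2] != dl[2] * config$scale)
    stop("high-res side must equal low-res side times `scale`")
  if (config$patch_size > dh[1] || config$patch_size > dh[2])
    stop(sprintf("patch size %d exceeds training image side %d",
                 config$patch_size, min(dh[1:2])))
  rng <- robust_range(lo$data)
  if (diff(rng) <= 0) stop("low-res training stack is constant")
  ns <- dh[3]; ps <- config$patch_size
  Lx <- lanczos_matrix(dl[1], config$scale)
  Ly <- lanczos_matrix(dl[2], config$scale)
  up <- array(0, dim = dh)
  for (s in seq_len(ns))
    up[, , s] <- Lx %*% normalize_frame(lo$data[, , s], rng) %*% t(Ly)
  hin <- normalize_frame(hi$data, rng)

  with_seed(config$seed, {
    genp <- gen_init(config)
    discp <- disc_init(config)
    gen_theta <- flatten_params(genp)
    disc_theta <- flatten_params(discp)
    gen_state <- adam_init(gen_theta)
    disc_state <- adam_init(disc_theta)

    sample_crop <- function() {
      s <- sample.int(ns, 1L)
      i <- sample.int(dh[1] - ps + 1L, 1L)
      j <- sample.int(dh[2] - ps + 1L, 1L)
      list(x = up[i:(i + ps - 1L), j:(j + ps - 1L), s],
           y = hin[i:(i + ps - 1L), j:(j + ps - 1L), s])
    }
    val_set <- lapply(seq_len(config$val_crops), function(i) sample_crop())

    add_tree <- function(a, b) {
      if (is.list(a)) return(mapply(add_tree, a, b, SIMPLIFY = FALSE))
      a + b
    }

    content_hist <- adv_hist <- d_hist <- numeric(config$iterations)
    val_hist <- NULL
    nb <- config$batch_size

    for (it in seq_len(config$iterations)) {
      batch <- lapply(seq_len(nb), function(k) sample_crop())
      fakes <- lapply(batch, function(bk) gen_forward(genp, bk$x, want_cache = TRUE))

      # --- discriminator step: real -> 1, generated -> 0
      d_grad <- NULL; d_loss <- 0
      for (k in seq_len(nb)) {
        fr <- disc_forward(discp, batch[[k]]$y, want_cache = TRUE)
        ff <- disc_forward(discp, fakes[[k]]$y[, , 1], want_cache = TRUE)
        d_loss <- d_loss + softplus(-fr$logit) + softplus(ff$logit)
        gr <- disc_backward(discp, fr$cache, sigmoid(fr$logit) - 1)$grads
        gf <- disc_backward(discp, ff$cache, sigmoid(ff$logit))$grads
        d_grad <- if (is.null(d_grad)) add_tree(gr, gf)
                  else add_tree(d_grad, add_tree(gr, gf))
      }
      d_hist[it] <- d_loss / nb
      upd <- adam_step(disc_theta, unlist(d_grad, use.names = FALSE) / nb,
                       disc_state, config$lr, config$adam_beta1,
                       config$adam_beta2)
      disc_theta <- upd$theta; disc_state <- upd$state
      discp <- unflatten_params(disc_theta, discp)

      # --- generator step: content MSE + adv_weight * BCE(D(fake), 1)
      g_grad <- NULL; c_loss <- 0; a_loss <- 0
      for (k in seq_len(nb)) {
        fake <- fakes[[k]]$y
        resid <- fake[, , 1] - batch[[k]]$y
        c_loss <- c_loss + mean(resid^2)
        ff <- disc_forward(discp, fake[, , 1], want_cache = TRUE)
        a_loss <- a_loss + softplus(-ff$logit)
        db <- disc_backward(discp, ff$cache, sigmoid(ff$logit) - 1)
        gy <- 2 * resid / length(resid) + config$adv_weight * db$gx[, , 1]
        dim(gy) <- c(dim(resid), 1L)
        gg <- gen_backward(genp, fakes[[k]]$cache, gy)
        g_grad <- if (is.null(g_grad)) gg else add_tree(g_grad, gg)
      }
      content_hist[it] <- c_loss / nb
      adv_hist[it] <- a_loss / nb
      if (!is.finite(content_hist[it]))
        stop(sprintf("training diverged (non-finite content loss at iteration %d)", it))
      upd <- adam_step(gen_theta, unlist(g_grad, use.names = FALSE) / nb,
                       gen_state, config$lr, config$adam_beta1,
                       config$adam_beta2)
      gen_theta <- upd$theta; gen_state <- upd$state
      genp <- unflatten_params(gen_theta, genp)

      if (it %% config$val_interval == 0L || it == config$iterations) {
        vl <- mean(vapply(val_set, function(v)
          mean((gen_forward(genp, v$x)[, , 1] - v$y)^2), numeric(1)))
        val_hist <- rbind(val_hist, data.frame(iteration = it, val_loss = vl))
      }
    }

    structure(list(params = genp, config = config,
                   loss_history = content_hist, adv_history = adv_hist,
                   disc_history = d_hist, validation = val_hist,
                   scaling = rng,
                   architecture = architecture_table(genp, discp, config)),
              class = "trained_generator")
  })
}

#' @export
print.trained_generator <- function(x, ...) {
  cat(sprintf(
    "<trained_generator> scale %dx, %d resblocks (%d ch), %d iterations, final content loss %.3g\n",
    x$config$scale, x$config$n_resblocks, x$config$base_channels,
    x$config$iterations, tail(x$loss_history, 1)))
  invisible(x)
}

#' An untrained (identity-initialised) generator
#'
#' Builds the generator at its initialisation, without any training. Because
#' the output convolution starts near zero and the input is skipped through,
#' this model reproduces the Lanczos upscale almost exactly — the baseline
#' the adversarial training refines.
#'
#' @param config a [gan_config].
#' @param scaling intensity range (length-2) the model should assume.
#' @return A `trained_generator` with `iterations = 0` history.
#' @export
untrained_generator <- function(config = gan_config(), scaling = c(0, 1)) {
  genp <- with_seed(config$seed, gen_init(config))
  discp <- with_seed(config$seed, disc_init(config))
  structure(list(params = genp, config = config, loss_history = numeric(0),
                 adv_history = numeric(0), disc_history = numeric(0),
                 validation = NULL, scaling = scaling,
                 architecture = architecture_table(genp, discp, config)),
            class = "trained_generator")
}

#' Super-resolve a functional series frame by frame
#'
#' Every frame is normalised with the model's stored intensity scaling,
#' Lanczos-3-upscaled, passed through the trained generator, and mapped back
#' to the original intensity scale. The time dimension is untouched and the
#' pixel size divides by the scale factor.
#'
#' @param series a [functional_series] on the low-resolution grid.
#' @param gen a `trained_generator`.
#' @return The super-resolved [functional_series].
#' @export
superresolve_series <- function(series, gen) {
  stopifnot(inherits(series, "functional_series"),
            inherits(gen, "trained_generator"))
  d <- dim(series$data)
  sc <- gen$config$scale
  out <- array(0, dim = c(d[1] * sc, d[2] * sc, d[3], d[4]))
  Lx <- lanczos_matrix(d[1], sc)
  Ly <- lanczos_matrix(d[2], sc)
  rng <- gen$scaling
  for (s in seq_len(d[3])) for (t in seq_len(d[4])) {
    x <- Lx %*% normalize_frame(series$data[, , s, t], rng) %*% t(Ly)
    out[, , s, t] <- denormalize_frame(gen_forward(gen$params, x)[, , 1], rng)
  }
  # (per-frame path identical to superresolve_image, with the resampling
  # operators hoisted out of the loop)
  functional_series(out, tr = series$tr, pixel_size = series$pixel_size / sc,
                    slice_thickness = series$slice_thickness)
}

#' Super-resolve a single 2D image
#'
#' The per-frame path used by [superresolve_series()]: normalise with the
#' model's stored intensity scaling, Lanczos-3 upscale, refine through the
#' generator, undo the scaling.
#'
#' @param image 2D matrix on the low-resolution grid.
#' @param gen a `trained_generator`.
#' @return The super-resolved matrix (`side * scale`).
#' @export
superresolve_image <- function(image, gen) {
  stopifnot(is.matrix(image), inherits(gen, "trained_generator"))
  rng <- gen$scaling
  up <- upscale_lanczos(normalize_frame(image, rng), gen$config$scale)
  denormalize_frame(gen_forward(gen$params, up)[, , 1], rng)
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(peak^2 / MSE)` with `peak` defaulting to the dynamic range of
#' the reference `a`. Identical images return the 300 dB cap.
#'
#' @param a reference image (matrix or array).
#' @param b comparison image, same shape.
#' @param peak peak value; default `diff(range(a))` (1 is conventional for
#'   unit-range images).
#' @return PSNR in decibels, capped at 300.
#' @export
psnr <- function(a, b, peak = NULL) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  if (is.null(peak)) peak <- diff(range(a))
  mse <- mean((a - b)^2)
  if (mse == 0) return(300)
  min(10 * log10(peak^2 / mse), 300)
}

#' Save / load a trained model
#'
#' The checkpoint is a single RDS archive holding the generator parameters,
#' config, loss histories and intensity scaling.
#'
#' @param gen a `trained_generator`.
#' @param path file path.
#' @return [read_model()] returns the `trained_generator`.
#' @export
write_model <- function(gen, path) {
  stopifnot(inherits(gen, "trained_generator"))
  saveRDS(gen, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  gen <- readRDS(path)
  if (!inherits(gen, "trained_generator")) stop("not a trained_generator archive")
  gen
}
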