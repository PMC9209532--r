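# Internal neural-network plumbing for the super-resolution GAN.
# Images are (H, W, C) arrays; conv weights are (k*k*C_in, C_out) matrices
# (layout matched by src/nn_ops.cpp); all parameters live in nested lists of
# numeric leaves so Adam can work on the flattened vector.

lrelu <- function(x, slope = 0.2) {
  neg <- x < 0
  x[neg] <- slope * x[neg]
  x
}
lrelu_grad <- function(pre, g, slope = 0.2) {
  neg <- pre < 0
  g[neg] <- slope * g[neg]
  g
}
softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
sigmoid <- function(x) 1 / (1 + exp(-x))

conv_init <- function(k, c_in, c_out, gain = 1) {
  sd <- gain * sqrt(2 / (k * k * c_in))
  list(w = matrix(rnorm(k * k * c_in * c_out, 0, sd), k * k * c_in, c_out),
       b = numeric(c_out))
}

conv_fw <- function(x, p, stride = 1L, pad = 1L)
  nn_conv_fw(x, p$w, p$b, stride, pad)

conv_bw <- function(x, p, gout, stride = 1L, pad = 1L)
  nn_conv_bw(x, p$w, gout, stride, pad)

# ---- generator: head conv -> n residual blocks (conv-lrelu-conv + skip) ->
# mid conv + global feature skip -> output conv + global image skip.
# Input is the Lanczos-upscaled frame, so spatial size is preserved; the
# network learns the residual detail. No batch normalisation anywhere.
gen_init <- function(config) {
  C <- config$base_channels
  blocks <- lapply(seq_len(config$n_resblocks), function(i)
    list(c1 = conv_init(3, C, C), c2 = conv_init(3, C, C)))
  list(head = conv_init(3, 1, C),
       blocks = blocks,
       mid = conv_init(3, C, C),
       # near-zero init: an untrained generator is ~ the identity on its input
       out = conv_init(3, C, 1, gain = 0.001))
}

gen_forward <- function(p, x, want_cache = FALSE) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  a_head <- conv_fw(x, p$head)
  h0 <- lrelu(a_head)
  h <- h0
  bl <- vector("list", length(p$blocks))
  for (i in seq_along(p$blocks)) {
    a1 <- conv_fw(h, p$blocks[[i]]$c1)
    z1 <- lrelu(a1)
    a2 <- conv_fw(z1, p$blocks[[i]]$c2)
    if (want_cache) bl[[i]] <- list(h_in = h, a1 = a1, z1 = z1)
    h <- h + a2
  }
  a_mid <- conv_fw(h, p$mid)
  h2 <- a_mid + h0
  y <- x + conv_fw(h2, p$out)
  if (!want_cache) return(y)
  list(y = y, cache = list(x = x, a_head = a_head, h0 = h0, blocks = bl,
                           h_last = h, h2 = h2))
}

# gradient of all generator parameters given dL/dy
gen_backward <- function(p, cache, gy) {
  g <- list(head = NULL, blocks = vector("list", length(p$blocks)),
            mid = NULL, out = NULL)
  bo <- conv_bw(cache$h2, p$out, gy)
  g$out <- list(w = bo$gw, b = bo$gb)
  g_h2 <- bo$gx
  bm <- conv_bw(cache$h_last, p$mid, g_h2)
  g$mid <- list(w = bm$gw, b = bm$gb)
  g_h <- bm$gx
  for (i in rev(seq_along(p$blocks))) {
    cb <- cache$blocks[[i]]
    b2 <- conv_bw(cb$z1, p$blocks[[i]]$c2, g_h)
    g_a1 <- lrelu_grad(cb$a1, b2$gx)
    b1 <- conv_bw(cb$h_in, p$blocks[[i]]$c1, g_a1)
    g$blocks[[i]] <- list(c1 = list(w = b1$gw, b = b1$gb),
                          c2 = list(w = b2$gw, b = b2$gb))
    g_h <- g_h + b1$gx            # residual skip
  }
  g_h0 <- g_h + g_h2              # global feature skip
  g_a_head <- lrelu_grad(cache$a_head, g_h0)
  bh <- conv_bw(cache$x, p$head, g_a_head)
  g$head <- list(w = bh$gw, b = bh$gb)
  g
}

# ---- discriminator: n_conv 3x3 conv layers (stride 2 on every second
# layer, channels doubling up to 8x base), LeakyReLU, global average pool,
# dense -> real/fake logit. No batch normalisation.
disc_channel_plan <- function(n_conv, base) {
  mult <- pmin(2^(seq_len(n_conv) %/% 2), 8L)
  c_out <- base * mult
  c_in <- c(1L, head(c_out, -1))
  stride <- ifelse(seq_len(n_conv) %% 2 == 0, 2L, 1L)
  data.frame(c_in = c_in, c_out = c_out, stride = stride)
}

disc_init <- function(config) {
  plan <- disc_channel_plan(config$n_disc_conv, config$disc_base_channels)
  convs <- lapply(seq_len(nrow(plan)), function(i)
    conv_init(3, plan$c_in[i], plan$c_out[i]))
  list(convs = convs,
       dense = list(w = rnorm(plan$c_out[nrow(plan)], 0,
                              1 / sqrt(plan$c_out[nrow(plan)])), b = 0),
       plan = plan)
}

disc_forward <- function(d, x, want_cache = FALSE) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  cc <- vector("list", length(d$convs))
  h <- x
  for (i in seq_along(d$convs)) {
    a <- conv_fw(h, d$convs[[i]], stride = d$plan$stride[i], pad = 1L)
    if (want_cache) cc[[i]] <- list(h_in = h, a = a)
    h <- lrelu(a)
  }
  f <- apply(h, 3, mean)                     # global average pool
  logit <- sum(d$dense$w * f) + d$dense$b
  if (!want_cache) return(logit)
  list(logit = logit, cache = list(convs = cc, h_last = h, f = f))
}

disc_backward <- function(d, cache, dlogit) {
  g <- list(convs = vector("list", length(d$convs)),
            dense = list(w = dlogit * cache$f, b = dlogit))
  hd <- dim(cache$h_last)
  g_h <- array(rep(dlogit * d$dense$w / (hd[1] * hd[2]),
                   each = hd[1] * hd[2]), dim = hd)
  for (i in rev(seq_along(d$convs))) {
    cb <- cache$convs[[i]]
    g_a <- lrelu_grad(cb$a, g_h)
    bb <- conv_bw(cb$h_in, d$convs[[i]], g_a, stride = d$plan$stride[i])
    g$convs[[i]] <- list(w = bb$gw, b = bb$gb)
    g_h <- bb$gx
  }
  list(grads = g, gx = g_h)
}

# ---- Adam on flattened parameter lists (plan element excluded) ----
strip_plan <- function(p) { p$plan <- NULL; p }

adam_init <- function(theta) list(m = numeric(length(theta)),
                                  v = numeric(length(theta)), t = 0L)

adam_step <- function(theta, grad, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

flatten_params <- function(p) unlist(strip_plan(p), use.names = FALSE)

unflatten_params <- function(theta, skeleton) {
  pos <- 0L
  rec <- function(s) {
    if (is.list(s)) return(lapply(s, rec))
    k <- length(s)
    leaf <- theta[(pos + 1L):(pos + k)]
    pos <<- pos + k
    if (!is.null(dim(s))) dim(leaf) <- dim(s)
    leaf
  }
  out <- rec(strip_plan(skeleton))
  if (!is.null(skeleton$plan)) out$plan <- skeleton$plan
  out
}

# architecture table used for structural assertions and printing
architecture_table <- function(gen_params, disc_params, config) {
  gen_rows <- data.frame(
    component = "generator",
    layer = c("conv_head", "lrelu",
              rep(c("conv", "lrelu", "conv", "skip_add"),
                  config$n_resblocks),
              "conv_mid", "skip_add_global", "conv_out", "input_skip_add"),
    stringsAsFactors = FALSE)
  plan <- disc_params$plan
  disc_rows <- data.frame(
    component = "discriminator",
    layer = as.vector(rbind(sprintf("conv_s%d_c%d", plan$stride, plan$c_out),
                            rep("lrelu", nrow(plan)))),
    stringsAsFactors = FALSE)
  disc_rows <- rbind(disc_rows,
                     data.frame(component = "discriminator",
                                layer = c("global_avg_pool", "dense")))
  rbind(gen_rows, disc_rows)
}
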