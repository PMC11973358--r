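# Leaf layers of the in-package neural-network engine.
#
# A leaf module is a list with a `kind`, a `par` list of learnable arrays,
# and whatever hyperparameters it needs.  Forward functions return
# list(out, cache [, mod]) -- `mod` is returned when the layer carries
# running state (batch norm).  Backward functions return
# list(gx, grads) where `grads` mirrors `par`.
#
# Weight initialisation is Kaiming fan-out for convolutions and linear
# layers, unit scale / zero shift for normalisation layers.

kaiming_init <- function(dims, fan_out) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_out)), dim = dims)
}

nn_conv <- function(cin, cout, k, stride = 1L, pad = (k - 1L) %/% 2L,
                    groups = 1L, bias = FALSE, init = "kaiming") {
  if (cin %% groups != 0 || cout %% groups != 0)
    stopf("conv: groups (%d) must divide channels %d -> %d", groups, cin, cout)
  wd <- c(k, k, cin %/% groups, cout)
  w <- switch(init,
    kaiming = kaiming_init(wd, fan_out = k * k * cout / groups),
    zero = array(0, wd),
    stopf("unknown init '%s'", init))
  par <- list(w = w)
  if (bias) par$b <- numeric(cout)
  list(kind = "conv", cin = cin, cout = cout, k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad),
       groups = as.integer(groups), bias = bias, par = par)
}

conv_forward <- function(mod, x) {
  out <- conv2d_fwd_cpp(x, mod$par$w,
                        if (mod$bias) mod$par$b else NULL,
                        mod$stride, mod$pad, mod$groups)
  list(out = out, cache = x)
}

conv_backward <- function(mod, cache, gout) {
  r <- conv2d_bwd_cpp(cache, mod$par$w, gout, mod$bias,
                      mod$stride, mod$pad, mod$groups)
  g <- list(w = r$gw)
  if (mod$bias) g$b <- r$gb
  list(gx = r$gx, grads = g)
}

nn_bn <- function(c, eps = 1e-5, momentum = 0.1) {
  list(kind = "bn", c = as.integer(c), eps = eps, momentum = momentum,
       par = list(gamma = rep(1, c), beta = numeric(c)),
       running_mean = numeric(c), running_var = rep(1, c))
}

bn_forward <- function(mod, x, training) {
  d <- fm_dims(x)
  hw <- d[1] * d[2]
  x3 <- x
  dim(x3) <- c(hw, d[3], d[4])
  if (training) {
    n_eff <- hw * d[4]
    mu <- rowSums(colSums(x3)) / n_eff                 # per-channel mean
    ss <- rowSums(colSums(x3 * x3)) / n_eff
    v <- pmax(ss - mu^2, 0)
    mod$running_mean <- (1 - mod$momentum) * mod$running_mean + mod$momentum * mu
    mod$running_var <- (1 - mod$momentum) * mod$running_var + mod$momentum * v
  } else {
    mu <- mod$running_mean
    v <- mod$running_var
  }
  inv <- 1 / sqrt(v + mod$eps)
  xhat <- (x - bcast_channel(mu, d)) * bcast_channel(inv, d)
  out <- xhat * bcast_channel(mod$par$gamma, d) + bcast_channel(mod$par$beta, d)
  dim(out) <- d
  list(out = out, cache = list(xhat = xhat, inv = inv, d = d, training = training),
       mod = mod)
}

bn_backward <- function(mod, cache, gout) {
  d <- cache$d
  hw <- d[1] * d[2]
  g3 <- gout
  dim(g3) <- c(hw, d[3], d[4])
  gbeta <- rowSums(colSums(g3))
  gxh <- g3 * array(cache$xhat, dim = c(hw, d[3], d[4]))
  ggamma <- rowSums(colSums(gxh))
  if (cache$training) {
    n_eff <- hw * d[4]
    t1 <- gout - bcast_channel(gbeta / n_eff, d) -
      cache$xhat * bcast_channel(ggamma / n_eff, d)
    gx <- t1 * bcast_channel(mod$par$gamma * cache$inv, d)
  } else {
    gx <- gout * bcast_channel(mod$par$gamma * cache$inv, d)
  }
  dim(gx) <- d
  list(gx = gx, grads = list(gamma = ggamma, beta = gbeta))
}

relu_forward <- function(x) {
  out <- pmax(x, 0)
  list(out = out, cache = x > 0)
}

relu_backward <- function(cache, gout) gout * cache

nn_linear <- function(cin, cout, bias = TRUE, init = "kaiming") {
  w <- switch(init,
    kaiming = matrix(stats::rnorm(cin * cout, sd = sqrt(2 / cout)), cin, cout),
    zero = matrix(0, cin, cout),
    stopf("unknown init '%s'", init))
  par <- list(w = w)
  if (bias) par$b <- numeric(cout)
  list(kind = "linear", cin = cin, cout = cout, bias = bias, par = par)
}

# x: cin x N matrix -> cout x N.
linear_forward <- function(mod, x) {
  out <- crossprod(mod$par$w, x)
  if (mod$bias) out <- out + mod$par$b
  list(out = out, cache = x)
}

linear_backward <- function(mod, cache, gout) {
  g <- list(w = cache %*% t(gout))
  if (mod$bias) g$b <- rowSums(gout)
  list(gx = mod$par$w %*% gout, grads = g)
}

nn_maxpool <- function(k, stride, pad) {
  list(kind = "maxpool", k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad))
}

maxpool_forward <- function(mod, x) {
  r <- maxpool_fwd_cpp(x, mod$k, mod$stride, mod$pad)
  list(out = r$out, cache = list(idx = r$idx, h = dim(x)[1], w = dim(x)[2]))
}

maxpool_backward <- function(cache, gout) {
  maxpool_bwd_cpp(cache$idx, gout, cache$h, cache$w)
}

# Global average pool: (H,W,C,N) -> C x N matrix.
gap_forward <- function(x) {
  d <- fm_dims(x)
  hw <- d[1] * d[2]
  x3 <- x
  dim(x3) <- c(hw, d[3] * d[4])
  out <- matrix(colSums(x3) / hw, d[3], d[4])
  list(out = out, cache = d)
}

gap_backward <- function(cache, gout) {
  d <- cache
  gx <- rep(as.vector(gout) / (d[1] * d[2]), each = d[1] * d[2])
  dim(gx) <- d
  gx
}

# Softmax cross-entropy head. logits: K x N, labels: integer in 1..K.
softmax_cols <- function(logits) {
  z <- exp(sweep(logits, 2, apply(logits, 2, max)))
  sweep(z, 2, colSums(z), "/")
}

cross_entropy <- function(logits, labels) {
  p <- softmax_cols(logits)
  n <- ncol(logits)
  idx <- cbind(labels, seq_len(n))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  gl <- p
  gl[idx] <- gl[idx] - 1
  list(loss = loss, grad = gl / n, probs = p)
}
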