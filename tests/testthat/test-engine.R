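# The neural-network engine itself: convolution against a naive oracle,
# reverse-mode gradients against finite differences, batch-norm modes.

naive_conv <- function(x, w, b, stride, pad, groups) {
  d <- dim(x); K <- dim(w)[1]; Cinpg <- dim(w)[3]; Cout <- dim(w)[4]
  Ho <- (d[1] + 2 * pad - K) %/% stride + 1
  Wo <- (d[2] + 2 * pad - K) %/% stride + 1
  Coutpg <- Cout / groups
  out <- array(0, c(Ho, Wo, Cout, d[4]))
  for (n in 1:d[4]) for (co in 1:Cout) {
    g <- (co - 1) %/% Coutpg
    for (ho in 1:Ho) for (wo in 1:Wo) {
      s <- if (is.null(b)) 0 else b[co]
      for (ci in 1:Cinpg) for (kh in 1:K) for (kw in 1:K) {
        hi <- (ho - 1) * stride - pad + kh
        wi <- (wo - 1) * stride - pad + kw
        if (hi >= 1 && hi <= d[1] && wi >= 1 && wi <= d[2])
          s <- s + x[hi, wi, g * Cinpg + ci, n] * w[kh, kw, ci, co]
      }
      out[ho, wo, co, n] <- s
    }
  }
  out
}

test_that("grouped strided convolution matches a naive R implementation", {
  set.seed(80)
  cases <- list(list(k = 3L, s = 1L, p = 1L, g = 1L),
                list(k = 3L, s = 2L, p = 1L, g = 2L),
                list(k = 1L, s = 2L, p = 0L, g = 1L),
                list(k = 7L, s = 2L, p = 3L, g = 1L))
  for (cs in cases) {
    x <- array(rnorm(9 * 8 * 4 * 2), c(9, 8, 4, 2))
    w <- array(rnorm(cs$k^2 * (4 / cs$g) * 6), c(cs$k, cs$k, 4 / cs$g, 6))
    b <- rnorm(6)
    got <- sparcnet:::conv2d_fwd_cpp(x, w, b, cs$s, cs$p, cs$g)
    want <- naive_conv(x, w, b, cs$s, cs$p, cs$g)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("whole-network gradients agree with finite differences", {
  set.seed(81)
  cfg <- tiny_cfg("htrec")
  model <- build_network(cfg)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  labels <- c(1L, 3L)
  nf <- sparcnet:::network_forward_full
  fwd <- nf(model, x, training = TRUE)
  ce <- sparcnet:::cross_entropy(fwd$logits, labels)
  bwd <- sparcnet:::network_backward_full(model, fwd$caches, ce$grad, need_gx = TRUE)
  flat_g <- sparcnet:::flatten_grads(model, bwd$grads)
  flat_p <- flatten_params(model)
  expect_setequal(names(flat_g), names(flat_p))

  loss_at <- function(p) sparcnet:::cross_entropy(
    nf(set_params(model, p), x, training = TRUE)$logits, labels)$loss
  eps <- 1e-5
  set.seed(82)
  for (nm in sample(names(flat_p), 8)) {
    i <- sample(length(flat_p[[nm]]), 1)
    p1 <- flat_p; p1[[nm]][i] <- p1[[nm]][i] + eps
    p2 <- flat_p; p2[[nm]][i] <- p2[[nm]][i] - eps
    g_num <- (loss_at(p1) - loss_at(p2)) / (2 * eps)
    expect_lt(abs(flat_g[[nm]][i] - g_num),
              1e-3 * max(1, abs(g_num)))
  }
  # input gradient at a few pixels
  for (i in c(11L, 500L, 2900L)) {
    x1 <- x; x1[i] <- x[i] + eps
    x2 <- x; x2[i] <- x[i] - eps
    g_num <- (sparcnet:::cross_entropy(nf(model, x1, TRUE)$logits, labels)$loss -
              sparcnet:::cross_entropy(nf(model, x2, TRUE)$logits, labels)$loss) /
      (2 * eps)
    expect_lt(abs(bwd$gx[i] - g_num), 1e-5 * max(1, abs(g_num)))
  }
})

test_that("batch norm switches between batch and running statistics", {
  set.seed(83)
  bn <- sparcnet:::nn_bn(3L)
  x <- rand_fm(4, 4, 3, 5)
  f_tr <- sparcnet:::bn_forward(bn, x, training = TRUE)
  # per-channel batch statistics are removed
  x3 <- f_tr$out; dim(x3) <- c(16, 3, 5)
  mu <- rowSums(colSums(x3)) / (16 * 5)
  expect_equal(unname(mu), rep(0, 3), tolerance = 1e-10)
  # running buffers moved toward the batch statistics
  expect_false(all(f_tr$mod$running_mean == 0))
  # eval mode with fresh buffers is a pure affine map
  f_ev <- sparcnet:::bn_forward(bn, x, training = FALSE)
  expect_equal(f_ev$out, x / sqrt(1 + bn$eps), tolerance = 1e-12)
})

test_that("cross entropy gradient sums to zero per sample", {
  set.seed(84)
  logits <- matrix(rnorm(12), 3, 4)
  ce <- sparcnet:::cross_entropy(logits, c(1L, 2L, 3L, 1L))
  expect_equal(colSums(ce$grad), rep(0, 4), tolerance = 1e-12)
  expect_gt(ce$loss, 0)
})
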