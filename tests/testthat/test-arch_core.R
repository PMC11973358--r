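# Core architecture blocks: channel split, split-convolution + fusion,
# channel/spatial attention, bottleneck, whole-network contracts.

test_that("split_channels follows the ceiling rule and inverts by concatenation", {
  set.seed(1)
  x64 <- rand_fm(4, 4, 64, 1)
  s <- split_channels(x64, 0.5)
  expect_equal(dim(s$representative)[3], 32)
  expect_equal(dim(s$redundant)[3], 32)

  x3 <- rand_fm(4, 4, 3, 1)
  s3 <- split_channels(x3, 0.5)
  expect_equal(dim(s3$representative)[3], 2)  # ceiling(1.5)
  expect_equal(dim(s3$redundant)[3], 1)

  s1 <- split_channels(x3, 1)
  expect_equal(dim(s1$representative)[3], 3)
  expect_equal(dim(s1$redundant)[3], 0)

  expect_error(split_channels(x3, 0), "alpha")
  expect_error(split_channels(x3, 1.2), "alpha")

  # concatenation inverse, property over random alphas
  for (alpha in c(0.25, 0.5, 0.8)) {
    sp <- split_channels(x64, alpha)
    rec <- array(c(sp$representative, sp$redundant), dim = dim(x64))
    expect_identical(rec, x64)
  }
})

test_that("spconv_fuse is a convex per-channel combination with softmax weights", {
  set.seed(2)
  x <- rand_fm()
  # equal branches: output equals input regardless of weights
  expect_equal(spconv_fuse(x, x), x)

  # hand softmax: per-channel GAPs 2 and 0 -> weights (e^2/(e^2+1), 1/(e^2+1))
  a <- array(2, dim = c(3, 3, 1, 1))
  b <- array(0, dim = c(3, 3, 1, 1))
  w <- exp(2) / (exp(2) + 1)
  expect_equal(spconv_fuse(a, b)[1, 1, 1, 1], w * 2, tolerance = 1e-12)

  # all-zero inputs: weights (0.5, 0.5), output zero
  z <- array(0, dim = c(3, 3, 2, 1))
  expect_equal(spconv_fuse(z, z), z)

  expect_error(spconv_fuse(rand_fm(4, 4, 2, 1), rand_fm(4, 4, 3, 1)), "shape")

  # convexity envelope + weights sum to 1, over random draws
  for (i in 1:10) {
    y1 <- rand_fm(); y2 <- rand_fm()
    f <- sparcnet:::fuse_forward(y1, y2)
    expect_true(all(f$out >= pmin(y1, y2) - 1e-12))
    expect_true(all(f$out <= pmax(y1, y2) + 1e-12))
    expect_true(all(f$weights > 0 & f$weights < 1))
  }
})

test_that("spconv unit obeys shape and parameter contracts", {
  cfg <- arch_config("res_sp")
  set.seed(3)
  x <- rand_fm(8, 8, 64, 1)
  unit <- sparcnet:::make_spconv(64L, 64L, cfg, 1L)
  out <- sparcnet:::spconv_forward(unit, x, training = FALSE)$out
  expect_equal(dim(out), c(8, 8, 64, 1))

  out2 <- sparcnet:::spconv_forward(sparcnet:::make_spconv(64L, 64L, cfg, 2L),
                                    x, training = FALSE)$out
  expect_equal(dim(out2), c(4, 4, 64, 1))

  # weight-parameter count (ignoring bias/normalisation):
  # 9*32*64/2 + 32*64 + 32*64 = 13,312 vs 36,864 for a plain 3x3
  n_w <- length(unit$mods$gwc$par$w) + length(unit$mods$pwc$par$w) +
    length(unit$mods$red$par$w)
  expect_identical(n_w, 13312L)
  expect_identical(9L * 64L * 64L, 36864L)

  expect_error(sparcnet:::make_spconv(64L, 64L,
    arch_config("baseline", spconv_groups = 7L), 1L), "divide")
})

test_that("channel attention matches forced values and stays in (0,1)", {
  set.seed(4)
  x <- rand_fm(5, 5, 8, 2)
  mlp0 <- sparcnet:::make_chatt(8L, 4L, init = "zero")
  w <- channel_attention(x, 4, mlp = mlp0)
  expect_true(all(w == 0.5))          # sigmoid(0) with zero MLP

  mlp <- sparcnet:::make_chatt(8L, 4L)
  w2 <- channel_attention(x, 4, mlp = mlp)
  expect_true(all(w2 > 0 & w2 < 1))
  expect_equal(dim(w2), c(8, 2))

  # spatially constant input: avg and max descriptors coincide, so the
  # pre-sigmoid logit doubles one MLP pass
  xc <- array(rep(rnorm(8), each = 25), dim = c(5, 5, 8, 1))
  f1 <- sparcnet:::linear_forward(mlp$mods$fc1, matrix(xc[1, 1, , 1], 8, 1))
  z1 <- sparcnet:::linear_forward(mlp$mods$fc2, pmax(f1$out, 0))$out
  expect_equal(as.vector(channel_attention(xc, 4, mlp = mlp)),
               as.vector(stats::plogis(2 * z1)), tolerance = 1e-12)

  expect_error(channel_attention(rand_fm(4, 4, 2, 1), 4), "reduction")
})

test_that("spatial attention respects padding, range and kernel parity", {
  set.seed(5)
  x <- rand_fm(7, 9, 6, 2)
  m <- spatial_attention(x, 7)
  expect_equal(dim(m), c(7, 9, 1, 2))
  expect_true(all(m > 0 & m < 1))

  m0 <- spatial_attention(array(1, dim = c(5, 5, 3, 1)), 3,
                          conv = sparcnet:::make_spatt(3L, init = "zero"))
  expect_true(all(m0 == 0.5))        # zero conv weights and bias

  expect_error(spatial_attention(x, 4), "odd")
})

test_that("cbam gates multiplicatively and preserves shape", {
  cfg <- tiny_cfg("res_cba")
  set.seed(6)
  x <- rand_fm(6, 6, 16, 2)
  mod0 <- sparcnet:::make_cbam(16L, cfg, init = "zero")
  out0 <- sparcnet:::cbam_forward(mod0, x)$out
  expect_equal(out0, 0.25 * x, tolerance = 1e-12)   # two sigmoid(0) gates

  out <- cbam(x, cfg)
  expect_equal(dim(out), dim(x))
  z <- x * 0
  expect_equal(cbam(z, cfg), z)                     # multiplicative gating
})

test_that("bottleneck preserves residual shapes and passes through when zeroed", {
  cfg <- tiny_cfg("htrec")
  set.seed(7)
  x <- rand_fm(8, 8, 16, 2)
  blk <- sparcnet:::make_bottleneck(16L, 4L, cfg, 1L)
  out <- sparcnet:::bottleneck_forward(blk, x, FALSE)$out
  expect_equal(dim(out), dim(x))

  blk2 <- sparcnet:::make_bottleneck(16L, 4L, cfg, 2L)
  out2 <- sparcnet:::bottleneck_forward(blk2, x, FALSE)$out
  expect_equal(dim(out2), c(4, 4, 16, 2))
  expect_true(blk2$has_down)

  # zeroed transform branch: block reduces to relu(identity shortcut)
  blkz <- zero_all_params(list(kind = "wrap", mods = list(b = blk)))$mods$b
  outz <- sparcnet:::bottleneck_forward(blkz, x, FALSE)$out
  expect_equal(outz, pmax(x, 0), tolerance = 1e-12)
})

test_that("build_network honours the stage geometry and head contract", {
  cfg <- tiny_cfg("baseline", input_size = 64L, width = 4L)
  set.seed(8)
  model <- build_network(cfg)
  x <- array(runif(64 * 64 * 3 * 2), dim = c(64, 64, 3, 2))
  full <- sparcnet:::network_forward_full(model, x)
  expect_equal(dim(full$logits), c(3, 2))
  expect_equal(dim(full$features), c(2, 2, 128, 2))  # 4*width*8 channels, /32 spatial

  # default full-size geometry: 16 bottlenecks, 2048-channel pre-pool map
  d <- describe_network(arch_config("baseline"))
  expect_equal(sum(d$kind == "add"), 16)
  expect_equal(d$out_channels[nrow(d) - 1], 2048)
  expect_equal(d$in_h[nrow(d) - 1], 7)
  expect_equal(sum(arch_config("baseline")$stage_depths), 16)

  # deterministic forward given fixed weights and input
  expect_identical(network_forward(model, x), network_forward(model, x))
})

test_that("saturating both CBAM gates recovers the un-attended network", {
  set.seed(9)
  base <- build_network(tiny_cfg("baseline"))
  attn <- build_network(tiny_cfg("res_cba"))
  # share every non-attention parameter
  attn <- set_params(attn, flatten_params(base))
  attn <- saturate_cbam(attn)
  x <- array(runif(32 * 32 * 3 * 2), dim = c(32, 32, 3, 2))
  expect_equal(network_forward(attn, x), network_forward(base, x),
               tolerance = 1e-9)
})

test_that("arch_config validates its invariants", {
  expect_error(arch_config("htrec", spconv_groups = 7L), "divide")
  expect_error(arch_config("res_cba", cbam_reduction = 10000L), "attended")
  expect_error(arch_config("baseline", cbam_spatial_kernel = 4L), "odd")
  expect_error(arch_config("baseline", stage_depths = c(1, 2)), "4 positive")
  expect_silent(arch_config("htrec"))
})

test_that("checkpoints round-trip through JSON", {
  set.seed(10)
  cfg <- tiny_cfg("htrec")
  model <- build_network(cfg)
  x <- array(runif(32 * 32 * 3), dim = c(32, 32, 3, 1))
  lg <- network_forward(model, x)
  path <- tempfile(fileext = ".json")
  save_checkpoint(model, path)
  model2 <- load_checkpoint(path)
  expect_equal(network_forward(model2, x), lg, tolerance = 1e-12)
})
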