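# Stochastic augmentation: flips, elastic deformation, random crops,
# seeded reproducibility of the pipeline.

test_that("flips are involutions that permute pixels", {
  m <- array(c(1, 3, 2, 4, 11, 13, 12, 14, 21, 23, 22, 24), dim = c(2, 2, 3))
  h <- flip(m, "horizontal")
  expect_equal(h[1, , 1], c(2, 1))     # [[a,b],[c,d]] -> [[b,a],[d,c]]
  expect_equal(h[2, , 1], c(4, 3))
  expect_equal(flip(h, "horizontal"), m)
  v <- flip(m, "vertical")
  expect_equal(flip(v, "vertical"), m)

  set.seed(40)
  img <- array(runif(24 * 24 * 3, 0, 255), dim = c(24, 24, 3))
  for (ax in c("horizontal", "vertical"))
    expect_equal(sort(as.vector(flip(img, ax))), sort(as.vector(img)))
})

test_that("elastic transform: zero magnitude is identity, seeds reproduce", {
  set.seed(41)
  img <- array(runif(32 * 32 * 3, 0, 255), dim = c(32, 32, 3))
  expect_identical(elastic_transform(img, alpha = 0, sigma = 8), img)
  expect_error(elastic_transform(img, 10, 0), "sigma")

  set.seed(7); a <- elastic_transform(img, 20, 6)
  set.seed(7); b <- elastic_transform(img, 20, 6)
  expect_identical(a, b)
  set.seed(8); c_ <- elastic_transform(img, 20, 6)
  expect_false(identical(a, c_))

  # mean intensity preserved within 2% on a smooth image (Monte Carlo, 20 seeds)
  sm <- array(0, dim = c(64, 64, 3))
  for (ch in 1:3)
    sm[, , ch] <- 120 + 60 * outer(sin(seq(0, pi, length.out = 64)),
                                   cos(seq(0, pi, length.out = 64)))
  rel <- sapply(1:20, function(s) {
    set.seed(s)
    w <- elastic_transform(sm, 30, 8)
    abs(mean(w) - mean(sm)) / mean(sm)
  })
  expect_true(all(rel < 0.02))
})

test_that("random crop-resize obeys scale, shape and determinism", {
  set.seed(42)
  img <- array(runif(48 * 48 * 3, 0, 255), dim = c(48, 48, 3))
  out <- random_crop_resize(img, c(0.5, 0.9), 32)
  expect_equal(dim(out), c(32, 32, 3))

  set.seed(9); a <- random_crop_resize(img, c(0.5, 0.9), 32)
  set.seed(9); b <- random_crop_resize(img, c(0.5, 0.9), 32)
  expect_identical(a, b)

  # full-scale crop equals a plain resize (window is the whole image)
  set.seed(10)
  full <- random_crop_resize(img, c(1, 1), 24)
  expect_equal(full, resize_to_input(img, 24), tolerance = 1e-12)

  expect_error(random_crop_resize(img, c(0, 0.5), 32), "scale")
})

test_that("the pipeline reduces to a resize when all stochastic parts are off", {
  set.seed(43)
  img <- array(runif(40 * 40 * 3, 0, 255), dim = c(40, 40, 3))
  cfg <- augment_config(elastic_alpha = 0, p_hflip = 0, p_vflip = 0,
                        crop_scale = c(1, 1), out_size = 32L)
  out <- augment_pipeline(img, cfg)
  expect_equal(out, pmin(pmax(resize_to_input(img, 32), 0), 255),
               tolerance = 1e-12)
})

test_that("pipeline output contract and epoch-to-epoch variety", {
  set.seed(44)
  img <- array(runif(40 * 40 * 3, 0, 255), dim = c(40, 40, 3))
  cfg <- augment_config(out_size = 32L)
  a <- augment_pipeline(img, cfg)   # stream advances between calls
  b <- augment_pipeline(img, cfg)
  expect_equal(dim(a), c(32, 32, 3))
  expect_true(min(a) >= 0 && max(a) <= 255)
  expect_false(identical(a, b))

  # reseeding reproduces the full augmented stream
  set.seed(45); s1 <- replicate(3, augment_pipeline(img, cfg), simplify = FALSE)
  set.seed(45); s2 <- replicate(3, augment_pipeline(img, cfg), simplify = FALSE)
  expect_identical(s1, s2)

  expect_error(augment_config(p_hflip = 2), "probabilities")
  expect_error(augment_config(crop_scale = c(0.9, 0.1)), "crop_scale")
  expect_error(augment_config(elastic_sigma = 0), "sigma")
})
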