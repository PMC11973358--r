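# Seeded generator of three texture-distinct H&E-palette image classes
# standing in for the CCA / HCC / Norm-L patches, so every pipeline stage
# is testable offline.  The archetypes are loose visual analogues only
# (duct-like rings on a pale field; dense dark-purple nuclei; regular
# low-frequency pink cords) -- they claim no biological fidelity, just
# learnable, well-separated class structure.

#' Synthetic dataset configuration
#'
#' @param n_per_class integer vector of 3 counts (classes `cca_like`,
#'   `hcc_like`, `norm_like`).
#' @param image_size square side length, at least 32 (default 224).
#' @param seed integer master seed; the generator is fully deterministic
#'   given it.
#' @param noise_sd additive Gaussian pixel noise, 0..255 scale
#'   (default 8).
#' @param imbalance_preset if `TRUE`, `n_per_class` is replaced by the
#'   historical training proportions 180 : 3380 : 1536 scaled by
#'   `imbalance_scale`.
#' @param imbalance_scale divisor applied to the preset counts.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_per_class = c(50L, 50L, 50L), image_size = 224L,
                             seed = 1L, noise_sd = 8,
                             imbalance_preset = FALSE, imbalance_scale = 10) {
  if (imbalance_preset)
    n_per_class <- as.integer(round(c(180, 3380, 1536) / imbalance_scale))
  if (length(n_per_class) != 3 || any(n_per_class < 0))
    stopf("n_per_class must be 3 non-negative counts")
  if (image_size < 32) stopf("image_size must be at least 32")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  structure(list(n_per_class = as.integer(n_per_class),
                 image_size = as.integer(image_size), seed = as.integer(seed),
                 noise_sd = noise_sd),
            class = "synthetic_config")
}

synth_class_names <- c("cca_like", "hcc_like", "norm_like")

# H&E-ish palette (R, G, B on 0..255)
.pal <- list(eosin_pale = c(238, 220, 230), eosin = c(230, 160, 190),
             hemat_dark = c(80, 40, 110), hemat = c(130, 90, 160),
             lumen = c(248, 244, 246))

disc_mask <- function(size, ch, cw, r_h, r_w) {
  h <- matrix(seq_len(size), size, size)
  w <- matrix(seq_len(size), size, size, byrow = TRUE)
  ((h - ch) / r_h)^2 + ((w - cw) / r_w)^2 <= 1
}

paint <- function(img, mask, col) {
  for (c in 1:3) {
    pl <- img[, , c]
    pl[mask] <- col[c]
    img[, , c] <- pl
  }
  img
}

flat_image <- function(size, col) {
  img <- array(0, dim = c(size, size, 3))
  for (c in 1:3) img[, , c] <- col[c]
  img
}

# Class archetypes ------------------------------------------------------------

synth_cca <- function(size) {
  img <- flat_image(size, .pal$eosin_pale)
  n_ducts <- sample(3:6, 1)
  for (i in seq_len(n_ducts)) {
    ch <- runif(1, 0.15, 0.85) * size; cw <- runif(1, 0.15, 0.85) * size
    r_out_h <- runif(1, 0.08, 0.16) * size; r_out_w <- runif(1, 0.08, 0.16) * size
    outer <- disc_mask(size, ch, cw, r_out_h, r_out_w)
    inner <- disc_mask(size, ch, cw, 0.6 * r_out_h, 0.6 * r_out_w)
    img <- paint(img, outer & !inner, .pal$hemat)   # epithelial ring
    img <- paint(img, inner, .pal$lumen)            # duct lumen
  }
  img
}

synth_hcc <- function(size) {
  img <- flat_image(size, .pal$eosin)
  # dense nuclear field: ~35% coverage regardless of image size
  r_mean <- 0.014 * size + 1
  n_nuc <- round(0.35 * size * size / (pi * r_mean^2))
  for (i in seq_len(n_nuc)) {
    ch <- runif(1, 1, size); cw <- runif(1, 1, size)
    r <- runif(1, 0.008, 0.02) * size + 1
    img <- paint(img, disc_mask(size, ch, cw, r, r), .pal$hemat_dark)
  }
  img
}

synth_norm <- function(size) {
  img <- flat_image(size, .pal$eosin)
  h <- matrix(seq_len(size), size, size)
  w <- matrix(seq_len(size), size, size, byrow = TRUE)
  phase <- runif(1, 0, 2 * pi)
  freq <- runif(1, 4, 6) * 2 * pi / size
  cords <- 0.5 + 0.5 * sin(freq * (h + 0.3 * w) + phase)   # regular sinusoid cords
  for (c in 1:3)
    img[, , c] <- (1 - 0.5 * cords) * img[, , c] + 0.5 * cords * .pal$eosin_pale[c]
  img
}

#' Generate one synthetic image
#'
#' @param class_idx 1 (duct-like), 2 (dense-nuclei) or 3 (regular-cord).
#' @param size side length.
#' @param noise_sd additive Gaussian noise, 0..255 scale.
#' @return `size x size x 3` image on `[0, 255]`.
#' @export
synth_image <- function(class_idx, size = 224L, noise_sd = 8) {
  img <- switch(class_idx, synth_cca(size), synth_hcc(size), synth_norm(size))
  if (noise_sd > 0) img <- img + array(rnorm(length(img), 0, noise_sd), dim(img))
  pmin(pmax(img, 0), 255)
}

#' Generate a directory-per-class synthetic dataset
#'
#' Writes PNGs under `out_dir/<class>/img_####.png` plus `manifest.csv`
#' (columns path, class, class_index, seed).  Fully deterministic given
#' `cfg$seed`: per-image seeds are derived from (seed, class, index).
#'
#' @param cfg a [synthetic_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest data frame.
#' @export
generate_dataset <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (k in 1:3) {
    cls <- synth_class_names[k]
    cls_dir <- file.path(out_dir, cls)
    dir.create(cls_dir, showWarnings = FALSE)
    for (i in seq_len(cfg$n_per_class[k])) {
      iseed <- derive_seed(cfg$seed, k, i)
      set.seed(iseed)
      img <- synth_image(k, cfg$image_size, cfg$noise_sd)
      p <- file.path(cls_dir, sprintf("img_%04d.png", i))
      write_image(img, p)
      rows[[length(rows) + 1L]] <- data.frame(
        path = p, class = cls, class_index = k - 1L, seed = iseed)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Generate a synthetic dataset in memory
#'
#' Same content as [generate_dataset()] without touching disk; used by
#' tests and the learning smoke checks.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `images` (list of arrays) and `labels`
#'   (0-based integer vector).
#' @export
generate_dataset_memory <- function(cfg) {
  imgs <- list(); labels <- integer()
  for (k in 1:3) {
    for (i in seq_len(cfg$n_per_class[k])) {
      set.seed(derive_seed(cfg$seed, k, i))
      imgs[[length(imgs) + 1L]] <- synth_image(k, cfg$image_size, cfg$noise_sd)
      labels <- c(labels, k - 1L)
    }
  }
  list(images = imgs, labels = labels, class_names = synth_class_names)
}

#' Separability check with a fixed tiny reference classifier
#'
#' Trains a small fixed convolutional network (independent of the main
#' model family) on a stratified 70/30 split of the dataset and returns
#' held-out accuracy.  The generator's default parameters are expected to
#' yield at least 0.90; very large noise drives it to chance (1/3).
#'
#' @param dataset a [generate_dataset_memory()] result (or list with
#'   `images`, `labels`).
#' @param seed RNG seed for the reference run.
#' @param epochs training epochs of the reference model.
#' @param size images are resized to `size` for the check.
#' @return held-out accuracy.
#' @export
separability_check <- function(dataset, seed = 7L, epochs = 4L, size = 32L) {
  labels <- dataset$labels
  if (length(unique(labels)) < 2) stopf("degenerate dataset: fewer than 2 classes")
  n <- length(labels)
  set.seed(seed)
  holdout <- unlist(lapply(split(seq_len(n), labels), function(idx)
    sample(idx, max(1, round(0.3 * length(idx))))))
  x_all <- images_to_batch(lapply(dataset$images, function(im)
    bilinear_resize_cpp(im, size, size)))
  ref <- make_reference_cnn(num_classes = length(unique(labels)))
  tr_idx <- setdiff(seq_len(n), holdout)
  ref <- train_reference_cnn(ref, x_all[, , , tr_idx, drop = FALSE],
                             labels[tr_idx], epochs = epochs, lr = 3e-3,
                             batch = 32L)
  logits <- reference_cnn_forward(ref, x_all[, , , holdout, drop = FALSE])$logits
  pred <- max.col(t(logits)) - 1L
  mean(pred == labels[holdout])
}

# A fixed tiny CNN, independent of the main architecture family:
# conv 3->8 s2 / relu / conv 8->16 s2 / relu / GAP / linear.
make_reference_cnn <- function(num_classes = 3L) {
  list(conv1 = nn_conv(3L, 8L, 3L, 2L, 1L, bias = TRUE),
       conv2 = nn_conv(8L, 16L, 3L, 2L, 1L, bias = TRUE),
       fc = nn_linear(16L, num_classes))
}

reference_cnn_forward <- function(ref, x) {
  c1 <- conv_forward(ref$conv1, x); r1 <- relu_forward(c1$out)
  c2 <- conv_forward(ref$conv2, r1$out); r2 <- relu_forward(c2$out)
  gp <- gap_forward(r2$out)
  fc <- linear_forward(ref$fc, gp$out)
  list(logits = fc$out,
       cache = list(c1 = c1$cache, r1 = r1$cache, c2 = c2$cache,
                    r2 = r2$cache, gp = gp$cache, fc = fc$cache))
}

train_reference_cnn <- function(ref, x, labels, epochs, lr, batch) {
  n <- dim(x)[4]
  ms <- lapply(c(conv1 = "conv1", conv2 = "conv2", fc = "fc"),
               function(nm) NULL)
  adam <- list()
  t <- 0
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (s in seq(1, n, by = batch)) {
      idx <- ord[s:min(s + batch - 1, n)]
      xb <- x[, , , idx, drop = FALSE]
      fwd <- reference_cnn_forward(ref, xb)
      ce <- cross_entropy(fwd$logits, labels[idx] + 1L)
      fb <- linear_backward(ref$fc, fwd$cache$fc, ce$grad)
      gg <- gap_backward(fwd$cache$gp, fb$gx)
      g2 <- relu_backward(fwd$cache$r2, gg)
      cb2 <- conv_backward(ref$conv2, fwd$cache$c2, g2)
      g1 <- relu_backward(fwd$cache$r1, cb2$gx)
      cb1 <- conv_backward(ref$conv1, fwd$cache$c1, g1)
      grads <- list(conv1 = cb1$grads, conv2 = cb2$grads, fc = fb$grads)
      t <- t + 1
      for (m in names(grads)) {
        for (pn in names(grads[[m]])) {
          key <- paste(m, pn)
          g <- grads[[m]][[pn]]
          st <- adam[[key]]
          if (is.null(st)) st <- list(m = 0 * g, v = 0 * g)
          st$m <- 0.9 * st$m + 0.1 * g
          st$v <- 0.999 * st$v + 0.001 * g * g
          ref[[m]]$par[[pn]] <- ref[[m]]$par[[pn]] -
            lr * (st$m / (1 - 0.9^t)) / (sqrt(st$v / (1 - 0.999^t)) + 1e-8)
          adam[[key]] <- st
        }
      }
    }
  }
  ref
}

#' Class-conditional colour / texture summary statistics
#'
#' Mean RGB per class and a coarse high-frequency energy measure (mean
#' absolute horizontal first difference of the green channel) -- used by
#' tests to assert the generator's classes are pairwise distinct.
#'
#' @param dataset a [generate_dataset_memory()] result.
#' @return data frame, one row per class.
#' @export
class_statistics <- function(dataset) {
  labs <- sort(unique(dataset$labels))
  rows <- lapply(labs, function(l) {
    imgs <- dataset$images[dataset$labels == l]
    mc <- rowMeans(vapply(imgs, function(im) c(mean(im[, , 1]), mean(im[, , 2]),
                                               mean(im[, , 3])), numeric(3)))
    hf <- mean(vapply(imgs, function(im) mean(abs(diff(im[, , 2]))), numeric(1)))
    data.frame(class_index = l, mean_r = mc[1], mean_g = mc[2], mean_b = mc[3],
               hf_energy = hf)
  })
  do.call(rbind, rows)
}
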