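# Stochastic training-time augmentation with seeded reproducibility:
# elastic deformation, horizontal/vertical flips, random crop-and-resize.
# All randomness flows through R's RNG; callers seed it (directly or via
# the per-sample stream derivation in the training loop).

#' Augmentation configuration
#'
#' Defaults deform visibly while keeping tissue texture recognisable:
#' displacement magnitude 30 px smoothed at scale 8 px, flips with
#' probability 0.5 each, crops keeping 70-100% of the area.
#'
#' @param elastic_alpha displacement magnitude in pixels (0 disables).
#' @param elastic_sigma Gaussian smoothing scale of the displacement
#'   field, in pixels (> 0).
#' @param p_hflip,p_vflip flip probabilities.
#' @param crop_scale `(low, high)` area fraction of the random crop.
#' @param out_size output side length after the final resize.
#' @return an `augment_config` list.
#' @export
augment_config <- function(elastic_alpha = 30, elastic_sigma = 8,
                           p_hflip = 0.5, p_vflip = 0.5,
                           crop_scale = c(0.7, 1), out_size = 224L) {
  if (elastic_alpha < 0) stopf("elastic_alpha must be >= 0")
  if (elastic_sigma <= 0) stopf("elastic_sigma must be > 0")
  if (any(c(p_hflip, p_vflip) < 0 | c(p_hflip, p_vflip) > 1))
    stopf("flip probabilities must lie in [0, 1]")
  if (length(crop_scale) != 2 || crop_scale[1] > crop_scale[2] ||
      crop_scale[1] <= 0 || crop_scale[2] > 1)
    stopf("crop_scale must be (low, high) within (0, 1]")
  structure(list(elastic_alpha = elastic_alpha, elastic_sigma = elastic_sigma,
                 p_hflip = p_hflip, p_vflip = p_vflip, crop_scale = crop_scale,
                 out_size = as.integer(out_size)),
            class = "augment_config")
}

#' Elastic deformation
#'
#' Two independent uniform(-1, 1) displacement fields are Gaussian
#' smoothed at scale `sigma`, scaled by `alpha` and applied by bilinear
#' warping with edge replication.  Identical RNG state gives identical
#' output; `alpha = 0` is the identity.
#'
#' @param img `H x W x 3` image.
#' @param alpha displacement magnitude, pixels.
#' @param sigma smoothing scale, pixels (> 0).
#' @return deformed image.
#' @export
elastic_transform <- function(img, alpha = 30, sigma = 8) {
  if (sigma <= 0) stopf("sigma must be positive")
  if (alpha < 0) stopf("alpha must be >= 0")
  d <- dim(img)
  if (alpha == 0) return(img)
  dh <- gaussian_blur_cpp(matrix(runif(d[1] * d[2], -1, 1), d[1], d[2]), sigma) * alpha
  dw <- gaussian_blur_cpp(matrix(runif(d[1] * d[2], -1, 1), d[1], d[2]), sigma) * alpha
  base_h <- matrix(seq_len(d[1]) - 1, d[1], d[2])
  base_w <- matrix(seq_len(d[2]) - 1, d[1], d[2], byrow = TRUE)
  bilinear_warp_cpp(img, base_h + dh, base_w + dw)
}

#' Mirror an image about one axis
#'
#' `flip(flip(x, a), a)` is the identity; any flip permutes pixels so the
#' intensity histogram is unchanged.
#'
#' @param img `H x W x C` image.
#' @param axis `"horizontal"` (mirror left-right) or `"vertical"`.
#' @return flipped image.
#' @export
flip <- function(img, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  d <- dim(img)
  if (axis == "horizontal") img[, rev(seq_len(d[2])), , drop = FALSE]
  else img[rev(seq_len(d[1])), , , drop = FALSE]
}

#' Random crop followed by bilinear resize
#'
#' A window with area fraction drawn uniformly from `scale` is placed
#' uniformly inside the image, cropped, and resized to
#' `out_size x out_size`.  Windows smaller than 2 x 2 px trigger a retry
#' with a larger fraction (at most 10 attempts).
#'
#' @param img `H x W x 3` image.
#' @param scale `(low, high)` area fraction within (0, 1].
#' @param out_size output side length.
#' @return cropped-and-resized image.
#' @export
random_crop_resize <- function(img, scale = c(0.7, 1), out_size = 224L) {
  if (any(scale <= 0) || any(scale > 1) || scale[1] > scale[2])
    stopf("scale must be (low, high) within (0, 1]")
  d <- dim(img)
  for (attempt in 1:10) {
    frac <- runif(1, scale[1], scale[2])
    side <- sqrt(frac)
    ch <- max(1L, round(d[1] * side))
    cw <- max(1L, round(d[2] * side))
    if (ch >= 2 && cw >= 2) {
      h0 <- if (d[1] > ch) sample.int(d[1] - ch + 1L, 1L) else 1L
      w0 <- if (d[2] > cw) sample.int(d[2] - cw + 1L, 1L) else 1L
      crop <- img[h0:(h0 + ch - 1L), w0:(w0 + cw - 1L), , drop = FALSE]
      return(bilinear_resize_cpp(crop, as.integer(out_size), as.integer(out_size)))
    }
    scale <- c(min(1, scale[2]), 1)
  }
  stopf("random crop window smaller than 2 x 2 after 10 attempts")
}

#' Full stochastic augmentation pipeline
#'
#' In order: elastic deformation (whenever `elastic_alpha > 0`),
#' horizontal flip with `p_hflip`, vertical flip with `p_vflip`, random
#' crop-and-resize.  Each call consumes fresh randomness from R's RNG,
#' so repeated epochs see different variants of the same base image;
#' reseeding reproduces the full stream.
#'
#' @param img `H x W x 3` image on `[0, 255]`.
#' @param cfg an [augment_config()].
#' @return augmented `out_size x out_size x 3` image on `[0, 255]`.
#' @export
augment_pipeline <- function(img, cfg = augment_config()) {
  out <- img
  if (cfg$elastic_alpha > 0)
    out <- elastic_transform(out, cfg$elastic_alpha, cfg$elastic_sigma)
  if (cfg$p_hflip > 0 && runif(1) < cfg$p_hflip) out <- flip(out, "horizontal")
  if (cfg$p_vflip > 0 && runif(1) < cfg$p_vflip) out <- flip(out, "vertical")
  out <- random_crop_resize(out, cfg$crop_scale, cfg$out_size)
  pmin(pmax(out, 0), 255)
}
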