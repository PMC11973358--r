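# Deterministic image conditioning: adaptive gamma correction, median
# filtering, bilinear resizing to the network input size.  The pipeline
# order is fixed: gamma -> median -> resize; stochastic augmentation,
# when enabled, runs on the original image before the final resize.

#' Preprocessing configuration
#'
#' @param gamma_mode `"adaptive"` (exponent from the image's intensity
#'   distribution) or `"fixed"`.
#' @param gamma_fixed exponent used when `gamma_mode = "fixed"`.
#' @param gamma_clip length-2 clamp for the adaptive exponent; the
#'   default `c(0.5, 2)` guards against excessive contrast reduction on
#'   very dark or very bright patches.
#' @param median_kernel odd median-filter size (default 3, i.e. 3 x 3).
#' @param target_size square network input size (default 224).
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(gamma_mode = c("adaptive", "fixed"),
                              gamma_fixed = 1, gamma_clip = c(0.5, 2),
                              median_kernel = 3L, target_size = 224L) {
  gamma_mode <- match.arg(gamma_mode)
  if (gamma_fixed <= 0) stopf("gamma_fixed must be positive")
  if (length(gamma_clip) != 2 || gamma_clip[1] > gamma_clip[2])
    stopf("gamma_clip must be (low, high) with low <= high")
  if (median_kernel %% 2 == 0) stopf("median_kernel must be odd")
  if (target_size < 8) stopf("target_size must be at least 8")
  structure(list(gamma_mode = gamma_mode, gamma_fixed = gamma_fixed,
                 gamma_clip = gamma_clip, median_kernel = as.integer(median_kernel),
                 target_size = as.integer(target_size)),
            class = "preprocess_config")
}

#' Adaptive gamma exponent from the intensity distribution
#'
#' `gamma = log(0.5) / log(m)` with `m` the mean luminance on `[0, 1]`
#' (clamped to `[0.01, 0.99]`), clipped to `clip`.  A mid-grey image maps
#' to `gamma = 1`; darker images get `gamma < 1` (brightening), brighter
#' ones `gamma > 1`.
#'
#' @param img `H x W x 3` image on `[0, 255]`.
#' @param clip `(low, high)` clamp.
#' @return the exponent.
#' @export
adaptive_gamma <- function(img, clip = c(0.5, 2)) {
  raw_image_check(img)
  m <- mean(img) / 255
  m <- min(max(m, 0.01), 0.99)
  g <- log(0.5) / log(m)
  min(max(g, clip[1]), clip[2])
}

#' Apply a gamma curve
#'
#' Per channel, `out = round(255 * (in/255)^gamma)`; monotone in input
#' intensity with fixed endpoints 0 and 255.
#'
#' @param img `H x W x 3` image on `[0, 255]`.
#' @param gamma positive exponent.
#' @return transformed image.
#' @export
apply_gamma <- function(img, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0)
    stopf("gamma must be a positive number")
  out <- round(255 * (img / 255)^gamma)
  dim(out) <- dim(img)
  out
}

#' Median filter with edge-replication padding
#'
#' @param img `H x W x 3` image.
#' @param k odd kernel size, at most `min(H, W)`.
#' @return filtered image.
#' @export
median_filter <- function(img, k = 3L) {
  if (k %% 2 == 0) stopf("median kernel must be odd")
  d <- dim(img)
  if (k > min(d[1], d[2])) stopf("kernel larger than image")
  median_filter_cpp(img, as.integer(k))
}

#' Bilinear resize to the square network input
#'
#' Aspect ratio is not preserved (plain rescale to `size x size`).
#'
#' @param img `H x W x C` image.
#' @param size output side length, at least 8.
#' @return `size x size x C` image.
#' @export
resize_to_input <- function(img, size = 224L) {
  if (size < 8) stopf("size must be at least 8")
  bilinear_resize_cpp(img, as.integer(size), as.integer(size))
}

#' Full deterministic preprocessing pipeline
#'
#' gamma correction (adaptive or fixed) -> median filter -> resize.
#'
#' @param img `H x W x 3` image on `[0, 255]`.
#' @param cfg a [preprocess_config()].
#' @return `target_size x target_size x 3` image on `[0, 255]`.
#' @export
preprocess_image <- function(img, cfg = preprocess_config()) {
  raw_image_check(img)
  g <- if (cfg$gamma_mode == "adaptive") adaptive_gamma(img, cfg$gamma_clip)
       else cfg$gamma_fixed
  out <- apply_gamma(img, g)
  out <- median_filter(out, cfg$median_kernel)
  out <- resize_to_input(out, cfg$target_size)
  pmin(pmax(out, 0), 255)
}
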