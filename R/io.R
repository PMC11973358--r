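# Image file I/O.  In memory an image is a numeric H x W x 3 array on
# the 0..255 scale; on disk, 8-bit RGB PNG via the in-package codec.

#' Read / write an RGB image
#'
#' `read_image` accepts 8-bit non-interlaced greyscale/RGB/RGBA PNG
#' (greyscale replicated, alpha dropped); `write_image` writes 8-bit RGB
#' PNG.  Values are clamped to `[0, 255]` and rounded on write.
#'
#' @param path file path.
#' @return `read_image`: numeric `H x W x 3` array in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stopf("no such image file: '%s'", path)
  png_read_cpp(path.expand(path))
}

#' @rdname read_image
#' @param img numeric `H x W x 3` array.
#' @export
write_image <- function(img, path) {
  d <- dim(img)
  if (is.null(d) || length(d) != 3 || d[3] != 3)
    stopf("write_image expects an H x W x 3 array")
  png_write_cpp(path.expand(path), img)
  invisible(path)
}

raw_image_check <- function(img) {
  d <- dim(img)
  if (is.null(d) || length(d) != 3 || d[3] != 3)
    stopf("expected an H x W x 3 image array")
  if (d[1] < 8 || d[2] < 8) stopf("image must be at least 8 x 8")
  if (min(img) < 0 || max(img) > 255) stopf("pixel values must lie in [0, 255]")
  invisible(img)
}

# Stack H x W x 3 images into a (H, W, 3, N) feature batch on [0, 1].
images_to_batch <- function(imgs) {
  d <- dim(imgs[[1]])
  x <- array(0, dim = c(d[1], d[2], 3L, length(imgs)))
  for (i in seq_along(imgs)) x[, , , i] <- imgs[[i]] / 255
  x
}
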