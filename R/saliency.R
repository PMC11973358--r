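# Grad-CAM saliency over the final convolutional stage, with a
# blue-to-red overlay renderer.

#' Grad-CAM saliency map
#'
#' Pools the gradient of the target-class logit over the final
#' bottleneck stage's feature maps (taken after attention gating for the
#' attention-bearing variants) into per-channel weights, forms the
#' rectified weighted sum of the feature maps, min-max normalises to
#' `[0, 1]` and bilinearly upsamples to the input grid.  One class per
#' call.  If no activation contributes positive evidence the map is all
#' zeros and a warning is raised.
#'
#' @param model a trained [build_network()] model.
#' @param img `H x W x 3` image on `[0, 255]` (resized to the model's
#'   input size if needed).
#' @param target_class 0-based class index, or `"predicted"`.
#' @return a `saliency_map`: list with `weights` (H x W in `[0, 1]`),
#'   `target_class`, `source_layer`, `logits`.
#' @export
gradcam <- function(model, img, target_class = "predicted") {
  S <- model$cfg$input_size
  d <- dim(img)
  if (d[1] != S || d[2] != S) img <- resize_to_input(img, S)
  x <- images_to_batch(list(img))
  fwd <- network_forward_full(model, x, training = FALSE)
  K <- model$cfg$num_classes
  if (identical(target_class, "predicted"))
    target_class <- which.max(fwd$logits[, 1]) - 1L
  if (target_class < 0 || target_class >= K)
    stopf("target_class must lie in [0, %d)", K)
  glog <- matrix(0, K, 1)
  glog[target_class + 1L, 1] <- 1
  bwd <- network_backward_full(model, fwd$caches, glog)
  A <- fwd$features                            # h x w x C x 1
  G <- bwd$gfeatures
  da <- dim(A)
  alpha <- colMeans(matrix(G, da[1] * da[2], da[3]))   # pooled gradients
  map <- matrix(matrix(A, da[1] * da[2], da[3]) %*% alpha, da[1], da[2])
  map <- pmax(map, 0)
  if (max(map) <= 0) {
    warnf("no positive class evidence; returning a uniform zero map")
  } else {
    map <- (map - min(map)) / (max(map) - min(map))
  }
  up <- bilinear_resize_cpp(array(map, dim = c(da[1], da[2], 1L)), S, S)
  structure(list(weights = matrix(up, S, S),
                 target_class = as.integer(target_class),
                 source_layer = "stage4_output", logits = fwd$logits[, 1]),
            class = "saliency_map")
}

# blue (0) -> cyan -> green -> yellow -> red (1)
jetish_colormap <- function(v) {
  r <- pmin(pmax(1.5 - abs(4 * v - 3), 0), 1)
  g <- pmin(pmax(1.5 - abs(4 * v - 2), 0), 1)
  b <- pmin(pmax(1.5 - abs(4 * v - 1), 0), 1)
  cbind(r, g, b) * 255
}

#' Render a saliency overlay
#'
#' The map is run through a blue-to-red colormap and alpha-blended over
#' the image.
#'
#' @param img `H x W x 3` image on `[0, 255]`.
#' @param map a [gradcam()] result (or plain `H x W` matrix in `[0,1]`).
#' @param opacity blend factor in `[0, 1]`; 0 returns the image.
#' @return blended `H x W x 3` image.
#' @export
overlay <- function(img, map, opacity = 0.5) {
  if (opacity < 0 || opacity > 1) stopf("opacity must lie in [0, 1]")
  w <- if (inherits(map, "saliency_map")) map$weights else map
  d <- dim(img)
  if (!all(dim(w) == d[1:2])) {
    w <- matrix(bilinear_resize_cpp(array(w, dim = c(dim(w), 1L)), d[1], d[2]),
                d[1], d[2])
  }
  cols <- jetish_colormap(as.vector(w))
  heat <- array(cols, dim = c(d[1], d[2], 3))
  (1 - opacity) * img + opacity * heat
}

#' Write a side-by-side original / overlay panel
#'
#' @param img `H x W x 3` image.
#' @param map a [gradcam()] result.
#' @param path output PNG path.
#' @param opacity overlay opacity.
#' @return invisibly, `path`.
#' @export
write_saliency_panel <- function(img, map, path, opacity = 0.5) {
  ov <- overlay(img, map, opacity)
  d <- dim(img)
  panel <- array(255, dim = c(d[1], 2 * d[2] + 4, 3))
  panel[, seq_len(d[2]), ] <- img
  panel[, d[2] + 4 + seq_len(d[2]), ] <- ov
  write_image(panel, path)
}
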