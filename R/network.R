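# Whole-network assembly and execution.
#
# A model is list(kind = "network", cfg, mods = list(stem_conv, stem_bn,
# maxpool, s<stage>b<block>..., fc)).  Forward caches every intermediate
# needed for the reverse pass; the reverse pass returns a gradient tree
# mirroring the parameter tree.

#' Build a model variant
#'
#' Stem (7x7 stride-2 convolution to `base_width` channels, batch norm,
#' rectifier, 3x3 stride-2 max pool), four stages of bottleneck blocks
#' with depths `cfg$stage_depths` and mid-widths `base_width * c(1,2,4,8)`
#' (block output widths x4), global average pooling, and a linear head.
#' Initial weights are drawn from the current RNG state (set a seed for
#' reproducible builds).
#'
#' @param cfg an [arch_config()].
#' @return an object of class `sparcnet_model`.
#' @seealso [describe_network()] for the layer inventory that drives the
#'   analytic complexity counts, [network_forward()] for inference.
#' @export
build_network <- function(cfg) {
  if (!inherits(cfg, "arch_config")) stopf("cfg must be an arch_config")
  mods <- list(stem_conv = nn_conv(3L, cfg$base_width, 7L, 2L, 3L),
               stem_bn = nn_bn(cfg$base_width),
               stem_pool = nn_maxpool(3L, 2L, 1L))
  cin <- cfg$base_width
  for (s in 1:4) {
    mid <- cfg$mids[s]
    for (b in seq_len(cfg$stage_depths[s])) {
      stride <- if (s > 1 && b == 1) 2L else 1L
      mods[[sprintf("s%db%d", s, b)]] <- make_bottleneck(cin, mid, cfg, stride)
      cin <- 4L * mid
    }
  }
  mods$fc <- nn_linear(cin, cfg$num_classes, bias = TRUE)
  structure(list(kind = "network", cfg = cfg, feat_channels = cin, mods = mods),
            class = "sparcnet_model")
}

#' @export
print.sparcnet_model <- function(x, ...) {
  cat(sprintf("<sparcnet_model> %s, %d classes, %s params\n", x$cfg$variant,
              x$cfg$num_classes,
              format(sum(lengths(flatten_params(x))), big.mark = ",")))
  invisible(x)
}

# Forward pass with caches.  Returns list(logits, features, caches, model).
network_forward_full <- function(model, x, training = FALSE) {
  caches <- list()
  m <- model$mods
  cs <- conv_forward(m$stem_conv, x); caches$stem_conv <- cs$cache
  bs <- bn_forward(m$stem_bn, cs$out, training); m$stem_bn <- bs$mod
  caches$stem_bn <- bs$cache
  rs <- relu_forward(bs$out); caches$stem_relu <- rs$cache
  mp <- maxpool_forward(m$stem_pool, rs$out); caches$stem_pool <- mp$cache
  h <- mp$out
  block_names <- grep("^s[0-9]b", names(m), value = TRUE)
  for (nm in block_names) {
    r <- bottleneck_forward(m[[nm]], h, training)
    m[[nm]] <- r$mod
    caches[[nm]] <- r$cache
    h <- r$out
  }
  features <- h
  gp <- gap_forward(h); caches$gap <- gp$cache
  fc <- linear_forward(m$fc, gp$out); caches$fc <- fc$cache
  model$mods <- m
  list(logits = fc$out, features = features, caches = caches, model = model)
}

# Reverse pass.  Returns list(grads, gfeatures, gx); gfeatures is the
# gradient at the last bottleneck output (used by Grad-CAM).
network_backward_full <- function(model, caches, glogits, need_gx = FALSE) {
  m <- model$mods
  grads <- list()
  fb <- linear_backward(m$fc, caches$fc, glogits); grads$fc <- fb$grads
  gh <- gap_backward(caches$gap, fb$gx)
  gfeatures <- gh
  block_names <- rev(grep("^s[0-9]b", names(m), value = TRUE))
  for (nm in block_names) {
    r <- bottleneck_backward(m[[nm]], caches[[nm]], gh)
    grads[[nm]] <- r$grads
    gh <- r$gx
  }
  gx <- NULL
  gmp <- maxpool_backward(caches$stem_pool, gh)
  gr <- relu_backward(caches$stem_relu, gmp)
  bb <- bn_backward(m$stem_bn, caches$stem_bn, gr); grads$stem_bn <- bb$grads
  cb <- conv_backward(m$stem_conv, caches$stem_conv, bb$gx)
  grads$stem_conv <- cb$grads
  if (need_gx) gx <- cb$gx
  list(grads = grads, gfeatures = gfeatures, gx = gx)
}

#' Run a model on a batch of images
#'
#' @param model a [build_network()] model.
#' @param x input batch, `dim = c(H, W, 3, N)`, pixel scale `[0, 1]`.
#' @param training if `TRUE`, normalisation layers use batch statistics
#'   (the running statistics are *not* updated by this convenience
#'   wrapper; the training loop handles that).
#' @return `num_classes x N` matrix of logits.
#' @export
network_forward <- function(model, x, training = FALSE) {
  network_forward_full(model, x, training)$logits
}

# ---- parameter tree utilities ----------------------------------------------

#' Flatten all learnable parameters of a model into a named list
#'
#' Names are `/`-separated paths (e.g. `"s1b1/conv1/w"`); the inverse is
#' [set_params()].  Used by the optimiser, the checkpoint reader/writer,
#' and the parameter-count oracle check.
#'
#' @param model a model or any module subtree.
#' @param path internal recursion state.
#' @return named list of numeric arrays.
#' @export
flatten_params <- function(model, path = character()) {
  if (!is.null(model$par)) {
    out <- list()
    for (nm in names(model$par))
      out[[paste(c(path, nm), collapse = "/")]] <- model$par[[nm]]
    return(out)
  }
  out <- list()
  if (!is.null(model$mods))
    for (nm in names(model$mods))
      out <- c(out, flatten_params(model$mods[[nm]], c(path, nm)))
  out
}

flatten_grads <- function(model, grads, path = character()) {
  if (!is.null(model$par)) {
    out <- list()
    for (nm in names(model$par))
      out[[paste(c(path, nm), collapse = "/")]] <- grads[[nm]]
    return(out)
  }
  out <- list()
  if (!is.null(model$mods))
    for (nm in names(model$mods))
      if (!is.null(grads[[nm]]))
        out <- c(out, flatten_grads(model$mods[[nm]], grads[[nm]], c(path, nm)))
  out
}

#' Write a flat named parameter list back into a model
#'
#' @param model a model from [build_network()].
#' @param flat named list as produced by [flatten_params()].
#' @return the updated model.
#' @export
set_params <- function(model, flat) {
  for (nm in names(flat)) {
    parts <- strsplit(nm, "/", fixed = TRUE)[[1]]
    leaf <- parts[length(parts)]
    node_path <- parts[-length(parts)]
    expr <- "model"
    for (p in node_path) expr <- paste0(expr, "$mods[['", p, "']]")
    expr <- paste0(expr, "$par[['", leaf, "']]")
    old <- eval(parse(text = expr))
    if (!identical(dim(old), dim(flat[[nm]])) && length(old) != length(flat[[nm]]))
      stopf("set_params: shape mismatch for '%s'", nm)
    eval(parse(text = paste0(expr, " <- flat[[nm]]")))
  }
  model
}

#' Save / load model weights
#'
#' Checkpoints are plain-text JSON: the flattened parameter list plus the
#' normalisation layers' running statistics and the architecture
#' configuration, so a checkpoint is self-describing and portable.
#'
#' @param model a model.
#' @param path file path (conventionally `.json`).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a rebuilt model.
#' @export
save_checkpoint <- function(model, path) {
  flat <- flatten_params(model)
  ser <- lapply(flat, function(a) list(dim = dim(a) %||% length(a),
                                       data = as.vector(a)))
  bufs <- collect_bn_buffers(model)
  obj <- list(config = unclass(model$cfg), params = ser, bn_buffers = bufs)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(arch_config, obj$config[c("variant", "num_classes", "input_size",
                                           "stage_depths", "spconv_alpha",
                                           "spconv_groups", "cbam_reduction",
                                           "cbam_spatial_kernel", "base_width")])
  model <- build_network(cfg)
  flat <- lapply(obj$params, function(p) {
    a <- as.double(p$data)
    if (length(p$dim) >= 2) dim(a) <- p$dim
    a
  })
  model <- set_params(model, flat)
  model <- restore_bn_buffers(model, obj$bn_buffers)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

collect_bn_buffers <- function(node, path = character()) {
  out <- list()
  if (identical(node$kind, "bn")) {
    out[[paste(path, collapse = "/")]] <-
      list(rm = node$running_mean, rv = node$running_var)
    return(out)
  }
  if (!is.null(node$mods))
    for (nm in names(node$mods))
      out <- c(out, collect_bn_buffers(node$mods[[nm]], c(path, nm)))
  out
}

restore_bn_buffers <- function(model, bufs) {
  for (nm in names(bufs)) {
    parts <- strsplit(nm, "/", fixed = TRUE)[[1]]
    expr <- "model"
    for (p in parts) expr <- paste0(expr, "$mods[['", p, "']]")
    eval(parse(text = paste0(expr, "$running_mean <- as.double(bufs[[nm]]$rm)")))
    eval(parse(text = paste0(expr, "$running_var <- as.double(bufs[[nm]]$rv)")))
  }
  model
}
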