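#' Architectural configuration for one model variant
#'
#' Describes one member of the model family built on a ResNet50-style
#' backbone: a plain bottleneck `baseline`, the split-convolution variant
#' `res_sp`, the channel/spatial-attention variant `res_cba`, and the
#' combined network `htrec`.
#'
#' @param variant one of `"baseline"`, `"res_sp"`, `"res_cba"`, `"htrec"`.
#' @param num_classes number of output classes (default 3: the
#'   cholangiocarcinoma / hepatocellular-carcinoma / normal-liver setting).
#' @param input_size square input size in pixels (default 224).
#' @param stage_depths number of bottleneck blocks per stage; the default
#'   `c(3, 4, 6, 3)` (sum 16) is the standard 50-layer backbone.
#' @param spconv_alpha fraction of channels routed to the representative
#'   (heavy 3x3) branch of the split convolution, in (0, 1]; default 0.5.
#' @param spconv_groups group count of the representative 3x3 convolution;
#'   must divide `ceiling(spconv_alpha * C)` for every bottleneck
#'   mid-width `C`.
#' @param cbam_reduction channel-attention bottleneck ratio `r`; the MLP
#'   hidden width is `floor(C / r)`.  Default 16 (the conventional
#'   choice); [calibrated_configs()] uses the ratio calibrated against the
#'   published complexity table.
#' @param cbam_spatial_kernel odd kernel size of the spatial-attention
#'   convolution (default 7).
#' @param base_width stem width; 64 is the full-size backbone.  Smaller
#'   values give "width-reduced" variants for desk-scale training (stage
#'   mid-widths are `base_width * c(1, 2, 4, 8)`).
#' @return an object of class `arch_config`.
#' @export
arch_config <- function(variant = c("baseline", "res_sp", "res_cba", "htrec"),
                        num_classes = 3L, input_size = 224L,
                        stage_depths = c(3L, 4L, 6L, 3L),
                        spconv_alpha = 0.5, spconv_groups = 2L,
                        cbam_reduction = 16L, cbam_spatial_kernel = 7L,
                        base_width = 64L) {
  variant <- match.arg(variant)
  if (!is_count(num_classes)) stopf("num_classes must be a positive integer")
  if (!is_count(input_size) || input_size < 32)
    stopf("input_size must be an integer >= 32")
  if (length(stage_depths) != 4L || !all(vapply(stage_depths, is_count, TRUE)))
    stopf("stage_depths must be 4 positive integers")
  if (!is.numeric(spconv_alpha) || spconv_alpha <= 0 || spconv_alpha > 1)
    stopf("spconv_alpha must lie in (0, 1]")
  if (!is_count(spconv_groups)) stopf("spconv_groups must be a positive integer")
  if (!is_count(cbam_reduction)) stopf("cbam_reduction must be a positive integer")
  if (!is_count(cbam_spatial_kernel) || cbam_spatial_kernel %% 2 == 0)
    stopf("cbam_spatial_kernel must be odd")
  if (!is_count(base_width)) stopf("base_width must be a positive integer")

  mids <- base_width * c(1L, 2L, 4L, 8L)
  if (variant %in% c("res_sp", "htrec")) {
    rep_ch <- ceiling(spconv_alpha * mids)
    bad <- mids[rep_ch %% spconv_groups != 0]
    if (length(bad))
      stopf("spconv_groups = %d does not divide the representative width for mid-channels %s",
            spconv_groups, paste(bad, collapse = ", "))
  }
  if (variant %in% c("res_cba", "htrec")) {
    smallest_attended <- 4L * mids[1]
    if (cbam_reduction > smallest_attended)
      stopf("cbam_reduction (%d) exceeds the smallest attended channel count (%d)",
            cbam_reduction, smallest_attended)
  }
  structure(list(variant = variant, num_classes = as.integer(num_classes),
                 input_size = as.integer(input_size),
                 stage_depths = as.integer(stage_depths),
                 spconv_alpha = spconv_alpha,
                 spconv_groups = as.integer(spconv_groups),
                 cbam_reduction = as.integer(cbam_reduction),
                 cbam_spatial_kernel = as.integer(cbam_spatial_kernel),
                 base_width = as.integer(base_width),
                 mids = as.integer(mids)),
            class = "arch_config")
}

#' @export
print.arch_config <- function(x, ...) {
  cat(sprintf("<arch_config> variant=%s classes=%d input=%dpx depths=%s width=%d\n",
              x$variant, x$num_classes, x$input_size,
              paste(x$stage_depths, collapse = "-"), x$base_width))
  if (x$variant %in% c("res_sp", "htrec"))
    cat(sprintf("  spconv: alpha=%.2f groups=%d\n", x$spconv_alpha, x$spconv_groups))
  if (x$variant %in% c("res_cba", "htrec"))
    cat(sprintf("  cbam: reduction=%d spatial kernel=%d\n",
                x$cbam_reduction, x$cbam_spatial_kernel))
  invisible(x)
}

#' Variant configurations calibrated to the published complexity table
#'
#' Returns the four full-size configurations used for complexity
#' profiling.  The channel-attention reduction ratio of the CBAM variants
#' is set to the calibrated value 42 (see [calibrate_cbam_reduction()]):
#' the ratio is not stated in the source description of the architecture,
#' and 42 is the integer at which both attention-bearing variants land on
#' the published parameter totals (hidden width `floor(C/42)`, no MLP
#' biases).
#'
#' @param num_classes classifier head width (default 3).
#' @return named list of four `arch_config` objects.
#' @export
calibrated_configs <- function(num_classes = 3L) {
  v <- c("baseline", "res_cba", "res_sp", "htrec")
  setNames(lapply(v, function(x)
    arch_config(x, num_classes = num_classes, cbam_reduction = 42L)), v)
}
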