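# Analytic parameter and FLOP accounting over a network description.
#
# Counting conventions (fixed; see the methods vignette for the
# calibration that pinned them down):
#   * parameters: conv K_h*K_w*C_in*C_out/groups (+C_out bias),
#     linear C_in*C_out + C_out, affine batch norm 2C, channel-attention
#     MLP 2*C*floor(C/r) (shared, no biases), spatial-attention conv
#     k*k*2 + 1; activations / pooling / elementwise steps carry none.
#   * FLOPs = 2 x [ conv & linear kernel multiply-accumulates (bias adds
#     excluded) + one fused op per element for batch norm and activation
#     outputs and per pooling *input* element ].  Parameter-free
#     elementwise steps (residual addition, split-branch fusion,
#     attention rescaling and its sigmoid) are not charged, matching the
#     module-hook behaviour of the common profiling tools that the
#     published table was produced with.

layer_params <- function(d) {
  k <- d$kind
  p <- numeric(nrow(d))
  conv_like <- k %in% c("conv", "grouped_conv", "pointwise_conv")
  p[conv_like] <- with(d[conv_like, , drop = FALSE],
    kernel_h * kernel_w * in_channels * out_channels / groups +
      ifelse(has_bias, out_channels, 0))
  p[k == "linear"] <- with(d[k == "linear", , drop = FALSE],
    in_channels * out_channels + out_channels)
  p[k == "batch_norm"] <- with(d[k == "batch_norm", , drop = FALSE],
    ifelse(affine, 2 * out_channels, 0))
  p[k == "channel_attention"] <- with(d[k == "channel_attention", , drop = FALSE],
    2 * in_channels * hidden)
  p[k == "spatial_attention"] <- with(d[k == "spatial_attention", , drop = FALSE],
    kernel_h * kernel_w * 2 + 1)
  known <- k %in% c("conv", "grouped_conv", "pointwise_conv", "linear",
                    "batch_norm", "channel_attention", "spatial_attention",
                    "activation", "pool", "global_pool", "add")
  if (!all(known)) stopf("unsupported layer kind: %s",
                         paste(unique(k[!known]), collapse = ", "))
  p
}

layer_flops <- function(d) {
  k <- d$kind
  f <- numeric(nrow(d))
  conv_like <- k %in% c("conv", "grouped_conv", "pointwise_conv")
  f[conv_like] <- with(d[conv_like, , drop = FALSE],
    2 * (kernel_h * kernel_w * in_channels * out_channels / groups) * out_h * out_w)
  f[k == "linear"] <- with(d[k == "linear", , drop = FALSE],
    2 * in_channels * out_channels)
  f[k == "batch_norm"] <- with(d[k == "batch_norm", , drop = FALSE],
    2 * out_channels * out_h * out_w)
  f[k == "activation"] <- with(d[k == "activation", , drop = FALSE],
    2 * out_channels * out_h * out_w)
  pool <- k %in% c("pool", "global_pool")
  f[pool] <- with(d[pool, , drop = FALSE], 2 * in_channels * in_h * in_w)
  f[k == "channel_attention"] <- with(d[k == "channel_attention", , drop = FALSE],
    2 * 2 * (2 * in_channels * hidden))            # two descriptor passes
  f[k == "spatial_attention"] <- with(d[k == "spatial_attention", , drop = FALSE],
    2 * (kernel_h * kernel_w * 2) * out_h * out_w)
  f
}

#' Count learnable parameters of a described network
#'
#' @param net a [describe_network()] description.
#' @return total integer parameter count.
#' @export
count_parameters <- function(net) {
  p <- sum(layer_params(net))
  if (p <= .Machine$integer.max) as.integer(p) else p
}

#' Count forward-pass FLOPs of a described network
#'
#' FLOPs are twice the multiply-accumulate count of the convolutional and
#' linear kernels plus doubled per-element costs for normalisation,
#' activation and pooling; see the vignette for the exact conventions.
#'
#' @param net a [describe_network()] description.
#' @param input_size optional square input size; must match the size the
#'   description was generated for.
#' @return FLOPs in units of 1e9 (GFLOPs).
#' @export
count_flops <- function(net, input_size = NULL) {
  cfg <- attr(net, "cfg")
  if (!is.null(input_size) && !is.null(cfg) && input_size != cfg$input_size)
    stopf("description was generated for input %d, not %d",
          cfg$input_size, input_size)
  sum(layer_flops(net)) / 1e9
}

#' Per-layer and total complexity report
#'
#' @param cfg an [arch_config()].
#' @return a `complexity_report`: list with `layers` (per-layer data
#'   frame including `params` and `flops`), `params` (integer total),
#'   `params_millions` and `flops_giga` (2-decimal totals).
#' @export
complexity_report <- function(cfg) {
  net <- describe_network(cfg)
  layers <- as.data.frame(net)
  layers$params <- layer_params(net)
  layers$flops <- layer_flops(net)
  total_p <- sum(layers$params)
  structure(list(layers = layers, params = total_p,
                 params_millions = round(total_p / 1e6, 2),
                 flops_giga = round(sum(layers$flops) / 1e9, 2),
                 variant = cfg$variant),
            class = "complexity_report")
}

#' @export
print.complexity_report <- function(x, ...) {
  cat(sprintf("<complexity_report> %s: %.2f M params, %.2f GFLOPs (%d layers)\n",
              x$variant, x$params_millions, x$flops_giga, nrow(x$layers)))
  invisible(x)
}

#' Model-family complexity table
#'
#' One row per configuration with totals in millions of parameters and
#' GFLOPs, mirroring the published comparison table layout.
#'
#' @param cfgs list of [arch_config()] objects (possibly empty). Defaults
#'   to [calibrated_configs()].
#' @return data frame with columns `Model`, `Params(M)`, `FLOPs(G)`.
#' @export
complexity_table <- function(cfgs = calibrated_configs()) {
  rows <- lapply(cfgs, function(cfg) {
    r <- complexity_report(cfg)
    data.frame(Model = variant_label(cfg$variant),
               `Params(M)` = r$params_millions,
               `FLOPs(G)` = r$flops_giga, check.names = FALSE)
  })
  if (!length(rows))
    return(data.frame(Model = character(), `Params(M)` = numeric(),
                      `FLOPs(G)` = numeric(), check.names = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

variant_label <- function(v) {
  switch(v, baseline = "Baseline", res_sp = "ResSPNet",
         res_cba = "ResCBANet", htrec = "HTRecNet", v)
}

#' Calibrate the channel-attention reduction ratio against target totals
#'
#' The reduction ratio of the attention MLP is not derivable from the
#' published architecture description; this helper scans integer ratios
#' and reports, for each, the parameter totals of the two
#' attention-bearing variants, plus which ratios reproduce the supplied
#' targets at two decimals.
#'
#' @param r_grid integer ratios to scan.
#' @param targets named numeric vector, in millions, for variants
#'   `res_cba` and `htrec` (defaults to the published 24.46 / 17.25).
#' @return list with `table` (per-ratio totals) and `calibrated`
#'   (ratios matching both targets; integer(0) if none).
#' @export
calibrate_cbam_reduction <- function(r_grid = 1:128,
                                     targets = c(res_cba = 24.46, htrec = 17.25)) {
  rows <- lapply(r_grid, function(r) {
    pc <- count_parameters(describe_network(arch_config("res_cba", cbam_reduction = r)))
    ph <- count_parameters(describe_network(arch_config("htrec", cbam_reduction = r)))
    data.frame(r = r, res_cba_millions = round(pc / 1e6, 2),
               htrec_millions = round(ph / 1e6, 2))
  })
  tab <- do.call(rbind, rows)
  hit <- tab$r[tab$res_cba_millions == targets[["res_cba"]] &
                 tab$htrec_millions == targets[["htrec"]]]
  list(table = tab, calibrated = hit)
}
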