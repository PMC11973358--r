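# NetworkDescription: an ordered layer inventory driving analytic
# parameter/FLOP counting.  describe_network() and build_network() are
# written against the same block recipe, and an oracle test asserts the
# counts agree with runtime enumeration of instantiated tensors.

new_descr_row <- function(kind, cin, cout, kh = NA, kw = NA, stride = 1L,
                          groups = 1L, bias = FALSE, affine = FALSE,
                          in_h = NA, in_w = NA, out_h = NA, out_w = NA,
                          hidden = NA) {
  data.frame(kind = kind, in_channels = cin, out_channels = cout,
             kernel_h = kh, kernel_w = kw, stride = stride, groups = groups,
             has_bias = bias, affine = affine, in_h = in_h, in_w = in_w,
             out_h = out_h, out_w = out_w, hidden = hidden,
             stringsAsFactors = FALSE)
}

#' Layer-by-layer description of a model variant
#'
#' Enumerates every layer of the network built by [build_network()] for
#' the same configuration, in execution order, with the channel, kernel,
#' stride, group, bias/affine and spatial-extent information needed for
#' analytic complexity accounting.  Parameter-free elementwise steps
#' (residual additions, branch fusion, attention rescaling) appear as
#' `add` rows.
#'
#' @param cfg an [arch_config()].
#' @return a `network_description`: a data frame of layer descriptors
#'   with attributes `cfg` and `total_stages`.
#' @export
describe_network <- function(cfg) {
  if (!inherits(cfg, "arch_config")) stopf("cfg must be an arch_config")
  rows <- list()
  S <- cfg$input_size
  emit <- function(...) rows[[length(rows) + 1L]] <<- new_descr_row(...)

  w0 <- cfg$base_width
  emit("conv", 3L, w0, 7L, 7L, 2L, in_h = S, in_w = S,
       out_h = S %/% 2L, out_w = S %/% 2L)
  S <- S %/% 2L
  emit("batch_norm", w0, w0, affine = TRUE, in_h = S, in_w = S, out_h = S, out_w = S)
  emit("activation", w0, w0, in_h = S, in_w = S, out_h = S, out_w = S)
  emit("pool", w0, w0, 3L, 3L, 2L, in_h = S, in_w = S,
       out_h = S %/% 2L, out_w = S %/% 2L)
  S <- S %/% 2L

  cin <- w0
  for (s in 1:4) {
    mid <- cfg$mids[s]
    cout <- 4L * mid
    for (b in seq_len(cfg$stage_depths[s])) {
      stride <- if (s > 1L && b == 1L) 2L else 1L
      S_in <- S
      S_out <- S %/% stride
      emit("pointwise_conv", cin, mid, 1L, 1L, 1L, in_h = S_in, in_w = S_in,
           out_h = S_in, out_w = S_in)
      emit("batch_norm", mid, mid, affine = TRUE, in_h = S_in, in_w = S_in,
           out_h = S_in, out_w = S_in)
      emit("activation", mid, mid, in_h = S_in, in_w = S_in,
           out_h = S_in, out_w = S_in)
      if (cfg$variant %in% c("res_sp", "htrec")) {
        n_rep <- as.integer(ceiling(cfg$spconv_alpha * mid))
        n_red <- mid - n_rep
        emit("grouped_conv", n_rep, mid, 3L, 3L, stride,
             groups = cfg$spconv_groups, bias = TRUE,
             in_h = S_in, in_w = S_in, out_h = S_out, out_w = S_out)
        emit("batch_norm", mid, mid, affine = TRUE, in_h = S_out, in_w = S_out,
             out_h = S_out, out_w = S_out)
        emit("pointwise_conv", n_rep, mid, 1L, 1L, stride, bias = TRUE,
             in_h = S_in, in_w = S_in, out_h = S_out, out_w = S_out)
        emit("batch_norm", mid, mid, affine = TRUE, in_h = S_out, in_w = S_out,
             out_h = S_out, out_w = S_out)
        if (n_red > 0L) {
          emit("pointwise_conv", n_red, mid, 1L, 1L, stride, bias = TRUE,
               in_h = S_in, in_w = S_in, out_h = S_out, out_w = S_out)
          emit("batch_norm", mid, mid, affine = TRUE, in_h = S_out, in_w = S_out,
               out_h = S_out, out_w = S_out)
          emit("add", mid, mid, in_h = S_out, in_w = S_out,  # soft-attention fusion
               out_h = S_out, out_w = S_out)
        }
        emit("activation", mid, mid, in_h = S_out, in_w = S_out,
             out_h = S_out, out_w = S_out)
      } else {
        emit("conv", mid, mid, 3L, 3L, stride, in_h = S_in, in_w = S_in,
             out_h = S_out, out_w = S_out)
        emit("batch_norm", mid, mid, affine = TRUE, in_h = S_out, in_w = S_out,
             out_h = S_out, out_w = S_out)
        emit("activation", mid, mid, in_h = S_out, in_w = S_out,
             out_h = S_out, out_w = S_out)
      }
      emit("pointwise_conv", mid, cout, 1L, 1L, 1L, in_h = S_out, in_w = S_out,
           out_h = S_out, out_w = S_out)
      emit("batch_norm", cout, cout, affine = TRUE, in_h = S_out, in_w = S_out,
           out_h = S_out, out_w = S_out)
      if (cfg$variant %in% c("res_cba", "htrec")) {
        emit("channel_attention", cout, cout, in_h = S_out, in_w = S_out,
             out_h = S_out, out_w = S_out,
             hidden = max(1L, cout %/% cfg$cbam_reduction))
        emit("spatial_attention", cout, cout, cfg$cbam_spatial_kernel,
             cfg$cbam_spatial_kernel, 1L, bias = TRUE,
             in_h = S_out, in_w = S_out, out_h = S_out, out_w = S_out)
      }
      if (cin != cout || stride != 1L) {
        emit("pointwise_conv", cin, cout, 1L, 1L, stride, in_h = S_in, in_w = S_in,
             out_h = S_out, out_w = S_out)
        emit("batch_norm", cout, cout, affine = TRUE, in_h = S_out, in_w = S_out,
             out_h = S_out, out_w = S_out)
      }
      emit("add", cout, cout, in_h = S_out, in_w = S_out,
           out_h = S_out, out_w = S_out)
      emit("activation", cout, cout, in_h = S_out, in_w = S_out,
           out_h = S_out, out_w = S_out)
      S <- S_out
      cin <- cout
    }
  }
  emit("global_pool", cin, cin, in_h = S, in_w = S, out_h = 1L, out_w = 1L)
  emit("linear", cin, cfg$num_classes, bias = TRUE,
       in_h = 1L, in_w = 1L, out_h = 1L, out_w = 1L)

  d <- do.call(rbind, rows)
  d$id <- seq_len(nrow(d))
  d <- d[, c("id", setdiff(names(d), "id"))]
  structure(d, cfg = cfg, total_stages = 4L,
            class = c("network_description", "data.frame"))
}
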