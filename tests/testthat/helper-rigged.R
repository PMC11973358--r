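# Constructed localisation fixture shared by the saliency and
# acceptance tests.

# Rig a tiny baseline model into a pure "centre-tap" pipeline: every
# convolution passes channel 1 through untouched (batch norms are
# identity in eval mode with default running statistics), the stem
# applies a -0.6 threshold so only bright pixels survive the rectifier,
# and the head reads the global average of channel 1.  The class-0 logit
# then depends only on where the input is bright.
rigged_model <- function() {
  cfg <- arch_config("baseline", num_classes = 2L, input_size = 64L,
                     stage_depths = c(1L, 1L, 1L, 1L), base_width = 4L)
  set.seed(60)
  model <- build_network(cfg)
  model <- zero_all_params(list(kind = "wrap", mods = list(m = model)))$mods$m
  flat <- flatten_params(model)
  # restore unit batch-norm scales
  for (nm in grep("/gamma$", names(flat), value = TRUE))
    flat[[nm]] <- flat[[nm]] * 0 + 1
  w <- flat[["stem_conv/w"]] ; w[4, 4, , 1] <- 1 / 3
  flat[["stem_conv/w"]] <- w
  flat[["stem_bn/beta"]][1] <- -0.6          # threshold: background clamps to 0
  for (blk in c("s1b1", "s2b1", "s3b1", "s4b1")) {
    for (cv in c("conv1", "conv3")) {
      w <- flat[[paste0(blk, "/", cv, "/w")]]
      w[1, 1, 1, 1] <- 1
      flat[[paste0(blk, "/", cv, "/w")]] <- w
    }
    w <- flat[[paste0(blk, "/mid/w")]]
    w[2, 2, 1, 1] <- 1
    flat[[paste0(blk, "/mid/w")]] <- w
  }
  flat[["fc/w"]][1, 1] <- 1
  model <- set_params(model, flat)
  class(model) <- "sparcnet_model"
  model
}

quadrant_image <- function() {
  # bright patch confined to the inner half of the top-left quadrant so
  # the strided centre-tap sampling lattice of the rigged model cannot
  # reach it from any other output cell
  img <- array(77, dim = c(64, 64, 3))          # mid-grey background
  set.seed(61)
  img[1:16, 1:16, ] <- 210 + array(runif(16 * 16 * 3, -20, 20), c(16, 16, 3))
  img
}

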