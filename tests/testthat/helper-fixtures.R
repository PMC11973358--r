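# Small shared fixtures, built in code.

tiny_cfg <- function(variant = "htrec", input_size = 32L, width = 4L,
                     depths = c(1L, 1L, 1L, 1L), r = 4L, sk = 3L) {
  arch_config(variant, num_classes = 3L, input_size = input_size,
              stage_depths = depths, base_width = width,
              cbam_reduction = r, cbam_spatial_kernel = sk)
}

rand_fm <- function(h = 6, w = 6, c = 4, n = 2) {
  array(stats::rnorm(h * w * c * n), dim = c(h, w, c, n))
}

# Two-class trivially separable image set: dark vs bright squares.
separable_images <- function(n_per = 10, size = 32, seed = 1) {
  set.seed(seed)
  imgs <- list(); labels <- integer()
  for (i in seq_len(n_per)) {
    imgs[[length(imgs) + 1L]] <- array(runif(size * size * 3, 20, 60),
                                       dim = c(size, size, 3))
    labels <- c(labels, 0L)
    imgs[[length(imgs) + 1L]] <- array(runif(size * size * 3, 180, 230),
                                       dim = c(size, size, 3))
    labels <- c(labels, 1L)
  }
  list(images = imgs, labels = labels)
}

zero_all_params <- function(model) {
  flat <- flatten_params(model)
  set_params(model, lapply(flat, function(a) a * 0))
}

# Force every CBAM gate in a model towards 1 (saturated sigmoids):
# channel MLP rows +/-M feeding an all-ones second layer, and a huge
# positive spatial-conv bias.
saturate_cbam <- function(model, M = 1e8) {
  flat <- flatten_params(model)
  for (nm in names(flat)) {
    if (grepl("cbam/ch/fc1/w$", nm)) {
      w <- flat[[nm]] * 0
      w[, 1] <- M
      if (ncol(w) >= 2) w[, 2] <- -M
      flat[[nm]] <- w
    } else if (grepl("cbam/ch/fc2/w$", nm)) {
      flat[[nm]] <- matrix(M, nrow(flat[[nm]]), ncol(flat[[nm]]))
    } else if (grepl("cbam/sp/conv/w$", nm)) {
      flat[[nm]] <- flat[[nm]] * 0
    } else if (grepl("cbam/sp/conv/b$", nm)) {
      flat[[nm]] <- flat[[nm]] * 0 + M
    }
  }
  set_params(model, flat)
}
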