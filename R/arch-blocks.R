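# Architecture building blocks: channel splitting, the split convolution
# (SPConv) with parameter-free soft-attention fusion, channel and spatial
# attention (CBAM), and the restructured residual bottleneck.
#
# Each composite module is a list(kind = ..., mods = list(...), ...);
# mod_forward()/mod_backward() dispatch over kinds (see nn-layers.R for
# the leaf layers).

#' Split a feature map into representative and redundant channel groups
#'
#' The first `ceiling(alpha * C)` channels (in index order) form the
#' representative part, the remainder the redundant part; concatenating
#' the two along the channel axis restores the input exactly.
#'
#' @param x feature map, `dim = c(H, W, C, N)`.
#' @param alpha representative fraction in (0, 1].
#' @return list with elements `representative` and `redundant` (the
#'   latter has zero channels when `alpha = 1`).
#' @export
split_channels <- function(x, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1)
    stopf("alpha must lie in (0, 1]")
  d <- fm_dims(x)
  if (alpha < 1 && d[3] < 2)
    stopf("need at least 2 channels to split when alpha < 1")
  n_rep <- as.integer(ceiling(alpha * d[3]))
  list(representative = x[, , seq_len(n_rep), , drop = FALSE],
       redundant = x[, , seq_len(d[3] - n_rep) + n_rep, , drop = FALSE])
}

#' Parameter-free fusion of the two split-convolution branches
#'
#' Per channel (and per sample), the global average of each branch is
#' taken as that branch's statistic; a softmax across the two statistics
#' yields convex weights, and the output is the weighted sum of the two
#' branches (weights broadcast over space).  No learnable parameters.
#'
#' @param y_rep,y_red feature maps of identical shape.
#' @return fused feature map of the same shape.
#' @export
spconv_fuse <- function(y_rep, y_red) {
  r <- fuse_forward(y_rep, y_red)
  r$out
}

fuse_forward <- function(y_rep, y_red) {
  d <- fm_dims(y_rep)
  if (!identical(d, fm_dims(y_red)))
    stopf("spconv_fuse: branch shapes differ (%s vs %s)",
          paste(dim(y_rep), collapse = "x"), paste(dim(y_red), collapse = "x"))
  s_rep <- gap_forward(y_rep)$out            # C x N
  s_red <- gap_forward(y_red)$out
  w_rep <- sigmoid(s_rep - s_red)            # softmax over the two statistics
  wr <- bcast_channel_batch(w_rep, d)
  out <- wr * y_rep + (1 - wr) * y_red
  dim(out) <- d
  list(out = out,
       cache = list(y_rep = y_rep, y_red = y_red, w_rep = w_rep, d = d),
       weights = w_rep)
}

fuse_backward <- function(cache, gout) {
  d <- cache$d
  hw <- d[1] * d[2]
  wr <- bcast_channel_batch(cache$w_rep, d)
  diff <- cache$y_rep - cache$y_red
  gdiff <- gout * diff
  dim(gdiff) <- c(hw, d[3] * d[4])
  # dL/da per (c, n), a = s_rep - s_red, w_rep = sigmoid(a)
  ga <- matrix(colSums(gdiff), d[3], d[4]) * cache$w_rep * (1 - cache$w_rep)
  gspread <- bcast_channel_batch(ga / hw, d)
  g_rep <- gout * wr + gspread
  g_red <- gout * (1 - wr) - gspread
  dim(g_rep) <- d; dim(g_red) <- d
  list(g_rep = g_rep, g_red = g_red)
}

# ---- split convolution unit -------------------------------------------------

make_spconv <- function(cin, cout, cfg, stride) {
  n_rep <- as.integer(ceiling(cfg$spconv_alpha * cin))
  n_red <- cin - n_rep
  if (n_rep %% cfg$spconv_groups != 0)
    stopf("spconv: groups (%d) must divide representative channels (%d)",
          cfg$spconv_groups, n_rep)
  mods <- list(
    gwc = nn_conv(n_rep, cout, 3L, stride, 1L, groups = cfg$spconv_groups,
                  bias = TRUE),
    bn_g = nn_bn(cout),
    pwc = nn_conv(n_rep, cout, 1L, stride, 0L, bias = TRUE),
    bn_p = nn_bn(cout))
  if (n_red > 0) {
    mods$red <- nn_conv(n_red, cout, 1L, stride, 0L, bias = TRUE)
    mods$bn_r <- nn_bn(cout)
  }
  list(kind = "spconv", cin = cin, cout = cout, n_rep = n_rep, n_red = n_red,
       stride = as.integer(stride), alpha = cfg$spconv_alpha, mods = mods)
}

spconv_forward <- function(mod, x, training) {
  xr <- x[, , seq_len(mod$n_rep), , drop = FALSE]
  f_g <- conv_forward(mod$mods$gwc, xr)
  b_g <- bn_forward(mod$mods$bn_g, f_g$out, training); mod$mods$bn_g <- b_g$mod
  f_p <- conv_forward(mod$mods$pwc, xr)
  b_p <- bn_forward(mod$mods$bn_p, f_p$out, training); mod$mods$bn_p <- b_p$mod
  y_rep <- b_g$out + b_p$out
  cache <- list(c_g = f_g$cache, c_bg = b_g$cache, c_p = f_p$cache,
                c_bp = b_p$cache, d_in = dim(x))
  if (mod$n_red > 0) {
    xd <- x[, , seq_len(mod$n_red) + mod$n_rep, , drop = FALSE]
    f_r <- conv_forward(mod$mods$red, xd)
    b_r <- bn_forward(mod$mods$bn_r, f_r$out, training); mod$mods$bn_r <- b_r$mod
    fz <- fuse_forward(y_rep, b_r$out)
    cache$c_r <- f_r$cache; cache$c_br <- b_r$cache; cache$c_fuse <- fz$cache
    out <- fz$out
  } else {
    out <- y_rep
  }
  list(out = out, cache = cache, mod = mod)
}

spconv_backward <- function(mod, cache, gout) {
  grads <- list()
  gx_red <- NULL
  if (mod$n_red > 0) {
    fb <- fuse_backward(cache$c_fuse, gout)
    g_rep <- fb$g_rep
    br <- bn_backward(mod$mods$bn_r, cache$c_br, fb$g_red)
    grads$bn_r <- br$grads
    cr <- conv_backward(mod$mods$red, cache$c_r, br$gx)
    grads$red <- cr$grads
    gx_red <- cr$gx
  } else {
    g_rep <- gout
  }
  bg <- bn_backward(mod$mods$bn_g, cache$c_bg, g_rep)
  grads$bn_g <- bg$grads
  cg <- conv_backward(mod$mods$gwc, cache$c_g, bg$gx)
  grads$gwc <- cg$grads
  bp <- bn_backward(mod$mods$bn_p, cache$c_bp, g_rep)
  grads$bn_p <- bp$grads
  cp <- conv_backward(mod$mods$pwc, cache$c_p, bp$gx)
  grads$pwc <- cp$grads

  gx <- array(0, dim = cache$d_in)
  gx[, , seq_len(mod$n_rep), ] <- cg$gx + cp$gx
  if (mod$n_red > 0)
    gx[, , seq_len(mod$n_red) + mod$n_rep, ] <- gx_red
  list(gx = gx, grads = grads)
}

#' Apply one split-convolution unit to a feature map
#'
#' Representative channels go through a grouped 3x3 convolution plus a
#' parallel pointwise 1x1 convolution (summed, each with its own batch
#' normalisation); redundant channels go through a cheap 1x1 convolution;
#' the branches are fused by [spconv_fuse()].  When `unit` is `NULL` a
#' fresh unit with `cout = C` is drawn from the current RNG state.
#'
#' @param x feature map.
#' @param cfg an [arch_config()].
#' @param stride 1 or 2.
#' @param unit optional pre-built unit from `make_spconv()`.
#' @param training use batch statistics in the normalisation layers.
#' @return feature map with `cout` channels at the strided spatial size.
#' @export
spconv <- function(x, cfg, stride = 1L, unit = NULL, training = FALSE) {
  if (!stride %in% c(1L, 2L)) stopf("stride must be 1 or 2")
  d <- fm_dims(x)
  if (is.null(unit)) unit <- make_spconv(d[3], d[3], cfg, stride)
  spconv_forward(unit, x, training)$out
}

# ---- channel attention ------------------------------------------------------

make_chatt <- function(C, r, init = "kaiming") {
  if (r > C) stopf("channel attention: reduction (%d) exceeds channels (%d)", r, C)
  hidden <- max(1L, C %/% r)
  list(kind = "chatt", c = as.integer(C), r = as.integer(r), hidden = hidden,
       mods = list(fc1 = nn_linear(C, hidden, bias = FALSE, init = init),
                   fc2 = nn_linear(hidden, C, bias = FALSE, init = init)))
}

chatt_forward <- function(mod, x) {
  d <- fm_dims(x)
  avg <- gap_forward(x)
  mx <- spatial_max_cpp(x)
  mlp_pass <- function(v) {
    f1 <- linear_forward(mod$mods$fc1, v)
    rl <- relu_forward(f1$out)
    f2 <- linear_forward(mod$mods$fc2, rl$out)
    list(out = f2$out, cache = list(c1 = f1$cache, cr = rl$cache, c2 = f2$cache))
  }
  pa <- mlp_pass(avg$out)
  pm <- mlp_pass(mx$max)
  w <- sigmoid(pa$out + pm$out)              # C x N
  list(out = w,
       cache = list(d = d, avg_cache = avg$cache, max_idx = mx$idx,
                    pa = pa$cache, pm = pm$cache, w = w))
}

chatt_backward <- function(mod, cache, gw) {
  d <- cache$d
  gz <- gw * cache$w * (1 - cache$w)
  mlp_back <- function(cc, g) {
    f2 <- linear_backward(mod$mods$fc2, cc$c2, g)
    rl <- relu_backward(cc$cr, f2$gx)
    f1 <- linear_backward(mod$mods$fc1, cc$c1, rl)
    list(gv = f1$gx, g1 = f1$grads, g2 = f2$grads)
  }
  ba <- mlp_back(cache$pa, gz)
  bm <- mlp_back(cache$pm, gz)
  grads <- list(fc1 = list(w = ba$g1$w + bm$g1$w),
                fc2 = list(w = ba$g2$w + bm$g2$w))
  gx <- gap_backward(cache$avg_cache, ba$gv)
  # scatter the max-descriptor gradient onto the argmax positions
  hw <- d[1] * d[2]
  flat_idx <- as.vector(cache$max_idx) + 1L +
    (seq_len(d[3] * d[4]) - 1L) * hw
  gx[flat_idx] <- gx[flat_idx] + as.vector(bm$gv)
  list(gx = gx, grads = grads)
}

#' Channel-attention weights
#'
#' Average-pooled and max-pooled channel descriptors pass through a shared
#' two-layer perceptron (`C -> floor(C/r) -> C`, rectifier between, no
#' biases); the sigmoid of the summed outputs gives one weight per channel
#' in (0, 1).
#'
#' @param x feature map.
#' @param r reduction ratio; must not exceed the channel count.
#' @param mlp optional module from `make_chatt()`; when `NULL` one is
#'   drawn from the current RNG state.
#' @return `C x N` matrix of weights in (0, 1).
#' @export
channel_attention <- function(x, r, mlp = NULL) {
  d <- fm_dims(x)
  if (is.null(mlp)) mlp <- make_chatt(d[3], r)
  chatt_forward(mlp, x)$out
}

# ---- spatial attention ------------------------------------------------------

make_spatt <- function(k, init = "kaiming") {
  if (k %% 2 == 0) stopf("spatial attention kernel must be odd")
  list(kind = "spatt", k = as.integer(k),
       mods = list(conv = nn_conv(2L, 1L, as.integer(k), 1L, (k - 1L) %/% 2L,
                                  bias = TRUE, init = init)))
}

# Sum a (hw, C, N) array over its channel dim -> hw x N matrix.
sum_channels3 <- function(x3) {
  d <- dim(x3)
  out <- matrix(0, d[1], d[3])
  for (n in seq_len(d[3])) out[, n] <- rowSums(x3[, , n, drop = FALSE])
  out
}

spatt_forward <- function(mod, x) {
  d <- fm_dims(x)
  hw <- d[1] * d[2]
  x3 <- x
  dim(x3) <- c(hw, d[3], d[4])
  mean_map <- sum_channels3(x3) / d[3]                # hw x N
  mx <- channel_max_cpp(x)
  desc <- array(0, dim = c(d[1], d[2], 2L, d[4]))
  desc[, , 1L, ] <- mean_map
  desc[, , 2L, ] <- mx$max
  cv <- conv_forward(mod$mods$conv, desc)
  s <- sigmoid(cv$out)                                 # H x W x 1 x N
  list(out = s, cache = list(d = d, conv_cache = cv$cache, max_idx = mx$idx, s = s))
}

spatt_backward <- function(mod, cache, gs) {
  d <- cache$d
  gz <- gs * cache$s * (1 - cache$s)
  cb <- conv_backward(mod$mods$conv, cache$conv_cache, gz)
  gdesc <- cb$gx                                       # H x W x 2 x N
  gmean <- gdesc[, , 1L, , drop = FALSE]
  gmax <- gdesc[, , 2L, , drop = FALSE]
  gx <- array(bcast_spatial(array(gmean, dim = c(d[1], d[2], 1, d[4])), d) / d[3],
              dim = d)
  hw <- d[1] * d[2]
  ci <- as.vector(cache$max_idx)                       # 0-based channel argmax per (hw, n)
  pos <- rep(seq_len(hw), times = d[4])
  nn <- rep(seq_len(d[4]) - 1L, each = hw)
  flat <- pos + ci * hw + nn * hw * d[3]
  gx[flat] <- gx[flat] + as.vector(gmax)
  list(gx = gx, grads = list(conv = cb$grads))
}

#' Spatial-attention map
#'
#' The channel-wise mean and maximum maps are stacked (2 channels) and
#' passed through a `k x k` convolution (padding `(k-1)/2`) to a single
#' channel, then a sigmoid.
#'
#' @param x feature map.
#' @param k odd kernel size.
#' @param conv optional module from `make_spatt()`.
#' @return array `dim = c(H, W, 1, N)` of weights in (0, 1).
#' @export
spatial_attention <- function(x, k, conv = NULL) {
  if (is.null(conv)) conv <- make_spatt(k)
  spatt_forward(conv, x)$out
}

# ---- CBAM -------------------------------------------------------------------

make_cbam <- function(C, cfg, init = "kaiming") {
  list(kind = "cbam", c = as.integer(C),
       mods = list(ch = make_chatt(C, cfg$cbam_reduction, init = init),
                   sp = make_spatt(cfg$cbam_spatial_kernel, init = init)))
}

cbam_forward <- function(mod, x) {
  d <- fm_dims(x)
  ch <- chatt_forward(mod$mods$ch, x)
  xp <- x * bcast_channel_batch(ch$out, d)
  dim(xp) <- d
  sp <- spatt_forward(mod$mods$sp, xp)
  out <- xp * bcast_spatial(sp$out, d)
  dim(out) <- d
  list(out = out,
       cache = list(d = d, x = x, xp = xp, ch = ch, sp = sp))
}

cbam_backward <- function(mod, cache, gout) {
  d <- cache$d
  hw <- d[1] * d[2]
  smap <- bcast_spatial(cache$sp$out, d)
  gxp <- gout * smap
  gy_xp <- gout * cache$xp                             # for the map gradient
  dim(gy_xp) <- c(hw, d[3], d[4])
  gsp <- array(sum_channels3(gy_xp), dim = c(d[1], d[2], 1, d[4]))
  sb <- spatt_backward(mod$mods$sp, cache$sp$cache, gsp)
  gxp <- gxp + sb$gx
  dim(gxp) <- d
  wch <- bcast_channel_batch(cache$ch$out, d)
  gx <- gxp * wch
  gxx <- gxp * cache$x
  dim(gxx) <- c(hw, d[3] * d[4])
  gwch <- matrix(colSums(gxx), d[3], d[4])
  cb <- chatt_backward(mod$mods$ch, cache$ch$cache, gwch)
  gx <- gx + cb$gx
  dim(gx) <- d
  list(gx = gx, grads = list(ch = cb$grads, sp = sb$grads))
}

#' Channel-then-spatial attention gating
#'
#' Applies channel attention first (`x' = x (*) w_c`), then spatial
#' attention (`y = x' (*) w_s`); shapes are preserved.
#'
#' @param x feature map with at least `cfg$cbam_reduction` channels.
#' @param cfg an [arch_config()].
#' @param module optional pre-built module from `make_cbam()`.
#' @return gated feature map, same shape as `x`.
#' @export
cbam <- function(x, cfg, module = NULL) {
  d <- fm_dims(x)
  if (d[3] < cfg$cbam_reduction)
    stopf("cbam: channels (%d) below reduction ratio (%d)", d[3], cfg$cbam_reduction)
  if (is.null(module)) module <- make_cbam(d[3], cfg)
  cbam_forward(module, x)$out
}

# ---- bottleneck -------------------------------------------------------------

make_bottleneck <- function(cin, mid, cfg, stride) {
  cout <- 4L * mid
  use_sp <- cfg$variant %in% c("res_sp", "htrec")
  use_cb <- cfg$variant %in% c("res_cba", "htrec")
  mods <- list(conv1 = nn_conv(cin, mid, 1L, 1L, 0L),
               bn1 = nn_bn(mid))
  if (use_sp) {
    mods$mid <- make_spconv(mid, mid, cfg, stride)
  } else {
    mods$mid <- nn_conv(mid, mid, 3L, stride, 1L)
    mods$bn2 <- nn_bn(mid)
  }
  mods$conv3 <- nn_conv(mid, cout, 1L, 1L, 0L)
  mods$bn3 <- nn_bn(cout)
  if (use_cb) mods$cbam <- make_cbam(cout, cfg)
  if (cin != cout || stride != 1L) {
    mods$down_conv <- nn_conv(cin, cout, 1L, stride, 0L)
    mods$down_bn <- nn_bn(cout)
  }
  list(kind = "bottleneck", cin = cin, mid = as.integer(mid), cout = cout,
       stride = as.integer(stride), use_sp = use_sp, use_cb = use_cb,
       has_down = !is.null(mods$down_conv), mods = mods)
}

bottleneck_forward <- function(mod, x, training) {
  c1 <- conv_forward(mod$mods$conv1, x)
  b1 <- bn_forward(mod$mods$bn1, c1$out, training); mod$mods$bn1 <- b1$mod
  r1 <- relu_forward(b1$out)
  cache <- list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache)
  if (mod$use_sp) {
    sp <- spconv_forward(mod$mods$mid, r1$out, training); mod$mods$mid <- sp$mod
    r2 <- relu_forward(sp$out)
    cache$mid <- sp$cache; cache$r2 <- r2$cache
  } else {
    c2 <- conv_forward(mod$mods$mid, r1$out)
    b2 <- bn_forward(mod$mods$bn2, c2$out, training); mod$mods$bn2 <- b2$mod
    r2 <- relu_forward(b2$out)
    cache$mid <- c2$cache; cache$b2 <- b2$cache; cache$r2 <- r2$cache
  }
  c3 <- conv_forward(mod$mods$conv3, r2$out)
  b3 <- bn_forward(mod$mods$bn3, c3$out, training); mod$mods$bn3 <- b3$mod
  y <- b3$out
  cache$c3 <- c3$cache; cache$b3 <- b3$cache
  if (mod$use_cb) {
    cb <- cbam_forward(mod$mods$cbam, y)
    y <- cb$out
    cache$cbam <- cb$cache
  }
  if (mod$has_down) {
    dc <- conv_forward(mod$mods$down_conv, x)
    db <- bn_forward(mod$mods$down_bn, dc$out, training); mod$mods$down_bn <- db$mod
    shortcut <- db$out
    cache$dc <- dc$cache; cache$db <- db$cache
  } else {
    if (!identical(dim(y), dim(x)))
      stopf("bottleneck: shape-incompatible shortcut without projection")
    shortcut <- x
  }
  s <- y + shortcut
  rf <- relu_forward(s)
  cache$rf <- rf$cache
  list(out = rf$out, cache = cache, mod = mod)
}

bottleneck_backward <- function(mod, cache, gout) {
  grads <- list()
  gs <- relu_backward(cache$rf, gout)
  gy <- gs
  if (mod$use_cb) {
    cb <- cbam_backward(mod$mods$cbam, cache$cbam, gy)
    grads$cbam <- cb$grads
    gy <- cb$gx
  }
  b3 <- bn_backward(mod$mods$bn3, cache$b3, gy); grads$bn3 <- b3$grads
  c3 <- conv_backward(mod$mods$conv3, cache$c3, b3$gx); grads$conv3 <- c3$grads
  g2 <- relu_backward(cache$r2, c3$gx)
  if (mod$use_sp) {
    sp <- spconv_backward(mod$mods$mid, cache$mid, g2)
    grads$mid <- sp$grads
    g1 <- sp$gx
  } else {
    b2 <- bn_backward(mod$mods$bn2, cache$b2, g2); grads$bn2 <- b2$grads
    c2 <- conv_backward(mod$mods$mid, cache$mid, b2$gx); grads$mid <- c2$grads
    g1 <- c2$gx
  }
  g1 <- relu_backward(cache$r1, g1)
  b1 <- bn_backward(mod$mods$bn1, cache$b1, g1); grads$bn1 <- b1$grads
  c1 <- conv_backward(mod$mods$conv1, cache$c1, b1$gx); grads$conv1 <- c1$grads
  gx <- c1$gx
  if (mod$has_down) {
    db <- bn_backward(mod$mods$down_bn, cache$db, gs); grads$down_bn <- db$grads
    dc <- conv_backward(mod$mods$down_conv, cache$dc, db$gx); grads$down_conv <- dc$grads
    gx <- gx + dc$gx
  } else {
    gx <- gx + gs
  }
  list(gx = gx, grads = grads)
}

#' Apply one residual bottleneck block
#'
#' Sequence (combined variant): 1x1 convolution -> 3x3 split convolution
#' -> 1x1 convolution -> CBAM -> residual addition -> rectifier, with
#' batch normalisation after each convolution stage.  `res_sp` omits
#' CBAM, `res_cba` keeps a plain 3x3 convolution, `baseline` does both.
#' The spatial stride lives in the 3x3 (or split-convolution) stage; a
#' strided 1x1 projection aligns the shortcut when shapes change.
#'
#' @param x feature map.
#' @param cfg an [arch_config()].
#' @param mid_channels bottleneck mid-width (output has `4 * mid_channels`).
#' @param stride 1 or 2.
#' @param block optional pre-built block from `make_bottleneck()`.
#' @param training use batch statistics in normalisation layers.
#' @return output feature map.
#' @export
bottleneck <- function(x, cfg, mid_channels, stride = 1L, block = NULL,
                       training = FALSE) {
  if (!stride %in% c(1L, 2L)) stopf("stride must be 1 or 2")
  d <- fm_dims(x)
  if (is.null(block)) block <- make_bottleneck(d[3], mid_channels, cfg, stride)
  bottleneck_forward(block, x, training)$out
}
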