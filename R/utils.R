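# Shared small helpers. Feature maps are numeric arrays dim = c(H, W, C, N).

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x >= 1 && x == round(x)

#' Construct a feature map array
#'
#' Feature maps are plain numeric arrays with `dim = c(H, W, C, N)`
#' (height, width, channels, batch).  This helper validates the invariants:
#' all four extents at least 1 and all values finite.
#'
#' @param values numeric vector or array of length `H*W*C*N`.
#' @param dim integer vector of length 4.
#' @return a validated feature-map array.
#' @export
feature_map <- function(values, dim) {
  if (length(dim) != 4L || any(dim < 1))
    stopf("feature map needs 4 extents, all >= 1")
  if (length(values) != prod(dim))
    stopf("feature map values (%d) do not fill dim (%s)",
          length(values), paste(dim, collapse = "x"))
  if (!all(is.finite(values))) stopf("feature map contains non-finite values")
  array(as.double(values), dim = as.integer(dim))
}

fm_dims <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 4L) stopf("expected a H x W x C x N feature map")
  d
}

# Broadcast a per-channel vector (length C) over a (H,W,C,N) array.
bcast_channel <- function(v, d) rep(rep(v, each = d[1] * d[2]), times = d[4])

# Broadcast a C x N matrix over space.
bcast_channel_batch <- function(m, d) rep(as.vector(m), each = d[1] * d[2])

# Broadcast a (H,W,1,N) map over channels.
bcast_spatial <- function(s, d) {
  hw <- d[1] * d[2]
  sm <- matrix(s, nrow = hw)                # hw x N
  as.vector(sm[, rep(seq_len(d[4]), each = d[3]), drop = FALSE])
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Seed derivation: fold sub-stream labels into a 32-bit-safe integer seed.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) h <- (h * 69069 + as.double(p) %% 2147483647) %% 2147483647
  as.integer(h)
}
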