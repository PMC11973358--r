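# Optimisers over flattened parameter lists (see flatten_params()).

#' Create an optimiser state
#'
#' `adam` (default) uses the usual bias-corrected first/second moments;
#' `sgd` is momentum gradient descent.  Weight decay is decoupled
#' (applied directly to the weights each step).
#'
#' @param kind "adam" or "sgd".
#' @param lr learning rate.
#' @param weight_decay decoupled weight-decay coefficient.
#' @param beta1,beta2,eps adam moments / numerical floor.
#' @param momentum sgd momentum.
#' @return an optimiser object.
#' @export
make_optimizer <- function(kind = c("adam", "sgd"), lr = 1e-3,
                           weight_decay = 0, beta1 = 0.9, beta2 = 0.999,
                           eps = 1e-8, momentum = 0.9) {
  kind <- match.arg(kind)
  list(kind = kind, lr = lr, weight_decay = weight_decay, beta1 = beta1,
       beta2 = beta2, eps = eps, momentum = momentum, t = 0L, state = list())
}

optimizer_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    p <- params[[nm]]
    if (opt$weight_decay > 0) p <- p - opt$lr * opt$weight_decay * p
    if (opt$kind == "adam") {
      st <- opt$state[[nm]]
      if (is.null(st)) st <- list(m = 0 * g, v = 0 * g)
      st$m <- opt$beta1 * st$m + (1 - opt$beta1) * g
      st$v <- opt$beta2 * st$v + (1 - opt$beta2) * g * g
      mhat <- st$m / (1 - opt$beta1^opt$t)
      vhat <- st$v / (1 - opt$beta2^opt$t)
      p <- p - opt$lr * mhat / (sqrt(vhat) + opt$eps)
      opt$state[[nm]] <- st
    } else {
      v <- opt$state[[nm]]
      if (is.null(v)) v <- 0 * g
      v <- opt$momentum * v + g
      p <- p - opt$lr * v
      opt$state[[nm]] <- v
    }
    params[[nm]] <- p
  }
  list(opt = opt, params = params)
}
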