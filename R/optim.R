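# Optimizers.
#
# The segmentation path trains with rectified Adam (RAdam) and per-epoch
# exponential learning-rate decay; the regression/classification parameters
# train with SGD + momentum, mirroring the dual-optimizer split of the
# training strategy.

#' SGD optimizer with momentum and weight decay
#'
#' @param params list of parameter nodes
#' @param lr learning rate
#' @param momentum momentum coefficient
#' @param weight_decay L2 coefficient added to the gradient
#' @return an optimizer object with a `$step()` method
#' @export
opt_sgd <- function(params, lr = 5e-4, momentum = 0.06, weight_decay = 5e-3) {
  vel <- lapply(params, function(p) p$v * 0)
  dims <- lapply(params, function(p) dim(p$v))
  env <- new.env(parent = emptyenv())
  env$lr <- lr
  env$step <- function() {
    for (i in seq_along(params)) {
      p <- params[[i]]
      if (is.null(p$grad)) next
      g <- as.numeric(p$grad) + weight_decay * as.numeric(p$v)
      vel[[i]] <<- momentum * as.numeric(vel[[i]]) + g
      new <- as.numeric(p$v) - env$lr * vel[[i]]
      dim(new) <- dims[[i]]
      p$v <- new
    }
  }
  class(env) <- "lvq_optimizer"
  env
}

#' Rectified Adam (RAdam) optimizer
#'
#' Standard RAdam: the adaptive step is rectified by the variance of the
#' exponential moving average length; early steps fall back to plain
#' momentum updates.
#'
#' @inheritParams opt_sgd
#' @param beta1,beta2 moment decay rates
#' @param eps numerical stabiliser
#' @return an optimizer object with a `$step()` method
#' @export
opt_radam <- function(params, lr = 5e-4, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 1e-4) {
  m <- lapply(params, function(p) as.numeric(p$v) * 0)
  v <- lapply(params, function(p) as.numeric(p$v) * 0)
  dims <- lapply(params, function(p) dim(p$v))
  env <- new.env(parent = emptyenv())
  env$lr <- lr
  env$t <- 0L
  rho_inf <- 2 / (1 - beta2) - 1
  env$step <- function() {
    env$t <- env$t + 1L
    t <- env$t
    rho_t <- rho_inf - 2 * t * beta2^t / (1 - beta2^t)
    for (i in seq_along(params)) {
      p <- params[[i]]
      if (is.null(p$grad)) next
      g <- as.numeric(p$grad) + weight_decay * as.numeric(p$v)
      m[[i]] <<- beta1 * m[[i]] + (1 - beta1) * g
      v[[i]] <<- beta2 * v[[i]] + (1 - beta2) * g * g
      mhat <- m[[i]] / (1 - beta1^t)
      new <- if (rho_t > 4) {
        r <- sqrt(((rho_t - 4) * (rho_t - 2) * rho_inf) /
                    ((rho_inf - 4) * (rho_inf - 2) * rho_t))
        vhat <- sqrt(v[[i]] / (1 - beta2^t)) + eps
        as.numeric(p$v) - env$lr * r * mhat / vhat
      } else {
        as.numeric(p$v) - env$lr * mhat
      }
      dim(new) <- dims[[i]]
      p$v <- new
    }
  }
  class(env) <- "lvq_optimizer"
  env
}
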