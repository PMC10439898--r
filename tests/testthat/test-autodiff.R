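# Reverse-mode tape: finite-difference gradient checks of every operator
# used by the networks, on tiny tensors.

num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim = dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
`%||%` <- function(a, b) if (is.null(a)) b else a

expect_grad <- function(build, inputs, tol = 1e-4) {
  nodes <- lapply(inputs, lvquant:::ad_param)
  loss <- build(nodes)
  lvquant:::ad_backward(loss)
  for (j in seq_along(inputs)) {
    f <- function(x) {
      n2 <- lapply(seq_along(inputs), function(k)
        lvquant:::ad_param(if (k == j) x else inputs[[k]]))
      lvquant:::ad_value(build(n2))
    }
    ng <- num_grad(f, inputs[[j]])
    ag <- nodes[[j]]$grad
    expect_lt(max(abs(ng - ag)) / max(1, max(abs(ng))), tol)
  }
}

sq_sum <- function(x) lvquant:::ad_sum(lvquant:::ad_pow2(x))

test_that("convolution, transposed convolution and pooling gradients", {
  set.seed(1)
  x <- array(rnorm(5 * 5 * 3 * 2 * 2), c(5, 5, 3, 2, 2))
  w <- array(rnorm(3 * 3 * 3 * 2 * 3) * 0.3, c(3, 3, 3, 2, 3))
  expect_grad(function(n) sq_sum(lvquant:::ad_conv3d(
    n[[1]], n[[2]], n[[3]], stride = c(1, 1, 1), pad = c(1, 1, 1))),
    list(x, w, rnorm(3)))
  ws <- array(rnorm(2 * 2 * 1 * 2 * 4) * 0.3, c(2, 2, 1, 2, 4))
  expect_grad(function(n) sq_sum(lvquant:::ad_conv3d(
    n[[1]], n[[2]], n[[3]], stride = c(2, 2, 1), pad = c(0, 0, 0))),
    list(x, ws, rnorm(4)))
  wt <- array(rnorm(2 * 2 * 1 * 3 * 2) * 0.3, c(2, 2, 1, 3, 2))
  expect_grad(function(n) sq_sum(lvquant:::ad_convt3d(
    n[[1]], n[[2]], n[[3]], stride = c(2, 2, 1))), list(x, wt, rnorm(3)))
  x4 <- array(rnorm(4 * 4 * 2 * 2 * 2), c(4, 4, 2, 2, 2))
  expect_grad(function(n) sq_sum(lvquant:::ad_maxpool(n[[1]], c(2, 2, 1))),
              list(x4))
})

test_that("normalisation gradients (group, batch, layer)", {
  set.seed(2)
  x <- array(rnorm(4 * 4 * 2 * 4 * 2), c(4, 4, 2, 4, 2))
  g4 <- rnorm(4); b4 <- rnorm(4)
  expect_grad(function(n) sq_sum(lvquant:::ad_groupnorm(
    n[[1]], n[[2]], n[[3]], groups = 2)), list(x, g4, b4))
  st <- new.env(); st$running_mean <- rep(0.2, 4); st$running_var <- rep(1.3, 4)
  expect_grad(function(n) sq_sum(lvquant:::ad_batchnorm(
    n[[1]], n[[2]], n[[3]], st, training = TRUE)), list(x, g4, b4))
  expect_grad(function(n) sq_sum(lvquant:::ad_batchnorm(
    n[[1]], n[[2]], n[[3]], st, training = FALSE)), list(x, g4, b4))
  tok <- array(rnorm(6 * 8 * 2), c(6, 8, 2))
  expect_grad(function(n) sq_sum(lvquant:::ad_layernorm(n[[1]], n[[2]], n[[3]])),
              list(tok, rnorm(8), rnorm(8)))
})

test_that("attention and token-dense gradients", {
  set.seed(3)
  tok <- array(rnorm(6 * 8 * 2), c(6, 8, 2))
  mats <- replicate(4, matrix(rnorm(64) * 0.3, 8, 8), simplify = FALSE)
  expect_grad(function(n) sq_sum(lvquant:::ad_mha(
    n[[1]], n[[2]], n[[3]], n[[4]], n[[5]], n[[6]], n[[7]], n[[8]], n[[9]],
    heads = 2)),
    c(list(tok), mats, list(rnorm(8), rnorm(8), rnorm(8), rnorm(8))))
  expect_grad(function(n) sq_sum(lvquant:::ad_dense_tokens(
    n[[1]], n[[2]], n[[3]])), list(tok, matrix(rnorm(24) * 0.3, 3, 8), rnorm(3)))
  expect_grad(function(n) sq_sum(lvquant:::ad_add_posemb(n[[1]], n[[2]])),
              list(tok, matrix(rnorm(48), 6, 8)))
})

test_that("shape, gating and reduction gradients", {
  set.seed(4)
  x <- array(rnorm(4 * 4 * 3 * 2 * 2), c(4, 4, 3, 2, 2))
  expect_grad(function(n) sq_sum(lvquant:::ad_softmax_c(n[[1]])), list(x))
  expect_grad(function(n) sq_sum(lvquant:::ad_concat_c(n[[1]], n[[2]])),
              list(x, array(rnorm(4 * 4 * 3 * 3 * 2), c(4, 4, 3, 3, 2))))
  expect_grad(function(n) sq_sum(lvquant:::ad_slice_t(n[[1]], 2:3)), list(x))
  expect_grad(function(n) sq_sum(lvquant:::ad_global_avgpool(n[[1]])), list(x))
  expect_grad(function(n) sq_sum(lvquant:::ad_scale_channels(n[[1]], n[[2]])),
              list(x, matrix(rnorm(4), 2, 2)))
  expect_grad(function(n) sq_sum(lvquant:::ad_sum_class(n[[1]])), list(x))
})

test_that("a full small unified model is differentiable end to end", {
  set.seed(5)
  model <- build_unified_model(test_seg_config(48L), test_reg_config())
  x <- array(rnorm(48 * 48 * 5), c(48, 48, 5, 1, 1))
  cls <- array(sample(0:2, 48 * 48 * 5, replace = TRUE), c(48, 48, 5, 1))
  y <- lvquant:::one_hot_masks(cls)
  t11 <- matrix(stats::runif(11), 11, 1)

  loss_of <- function() {
    out <- forward_unified(model, x, training = FALSE)  # fixed activations
    probs <- lvquant:::ad_softmax_c(out$seg$logits)
    ls <- seg_loss(probs, lvquant:::ad_const(y))
    psys <- lvquant:::ad_row(lvquant:::ad_softmax_rows(out$reg$phase_logits), 2L)
    lr <- reg_loss(out$reg$indices, lvquant:::ad_const(t11), psys, 1)
    unified_loss(ls, lr)
  }
  params <- lvquant:::collect_params(model[c("seg", "reg")])
  loss <- loss_of()
  lvquant:::ad_backward(loss)
  # spot-check one parameter from each path against finite differences
  for (nm in c("seg.stem.1.conv_a.w", "seg.pos", "reg.idx_out.w",
               "reg.st1.temporal.w")) {
    p <- params[[nm]]
    expect_false(is.null(p$grad))
    i <- which.max(abs(p$grad))
    eps <- 1e-4
    v0 <- p$v
    p$v[i] <- v0[i] + eps; lp <- lvquant:::ad_value(loss_of())
    p$v[i] <- v0[i] - eps; lm <- lvquant:::ad_value(loss_of())
    p$v <- v0
    fd <- (lp - lm) / (2 * eps)
    expect_equal(unname(p$grad[i]), unname(fd), tolerance = 5e-3)
  }
  # gradient from the unified loss reaches the segmentation stem through
  # both the segmentation loss and the fused regression features
  expect_gt(max(abs(params[["seg.stem.1.conv_a.w"]]$grad)), 0)
})
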