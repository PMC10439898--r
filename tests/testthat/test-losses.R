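# Joint loss: closed-form cases, brute-force loop oracles and gradients.

onehot5 <- function(classes, K = 3) {
  # classes: (H,W,T,N) integer array
  lvquant:::one_hot_masks(classes, K)
}

rand_probs <- function(d) {
  x <- array(stats::rexp(prod(d)), dim = d)
  den <- array(0, dim = d); K <- d[4]
  s <- x[, , , 1, , drop = FALSE]
  for (k in 2:K) s <- s + x[, , , k, , drop = FALSE]
  for (k in 1:K) x[, , , k, ] <- x[, , , k, ] / s[, , , 1, ]
  x
}

test_that("soft Dice loss matches its closed forms", {
  set.seed(1)
  cls <- array(sample(0:2, 4 * 4 * 2 * 2, replace = TRUE), c(4, 4, 2, 2))
  y <- onehot5(cls)
  expect_equal(soft_dice_loss(y, y), 0, tolerance = 1e-4)
  # fully disjoint prediction
  wrong <- onehot5((cls + 1L) %% 3L)
  expect_equal(soft_dice_loss(wrong, y), 1, tolerance = 1e-4)
  # uniform probabilities on a 2-pixel single-class image, by direct formula
  y2 <- array(0, c(2, 1, 1, 3, 1)); y2[, , , 1, ] <- 1
  p2 <- array(1 / 3, c(2, 1, 1, 3, 1))
  # per class k: 2*sum(y p)/(sum(y+p)): class0 (2*2/3)/(2+2/3), others 0/(2/3)
  expected <- 1 - (1 / 3) * ((4 / 3) / (8 / 3) + 0 + 0)
  expect_equal(soft_dice_loss(p2, y2), expected, tolerance = 1e-4)
  expect_error(soft_dice_loss(p2, y2[1, , , , , drop = FALSE]), "mismatch")
})

test_that("cross-entropy matches closed form and a scalar-loop oracle", {
  set.seed(2)
  cls <- array(sample(0:2, 4 * 4 * 2 * 2, replace = TRUE), c(4, 4, 2, 2))
  y <- onehot5(cls)
  expect_equal(cross_entropy_loss(y, y), 0, tolerance = 1e-8)
  u <- array(1 / 3, dim = dim(y))
  expect_equal(cross_entropy_loss(u, y), log(3), tolerance = 1e-6)
  p <- rand_probs(dim(y))
  loop <- 0; n <- 0
  for (i in 1:4) for (j in 1:4) for (t in 1:2) for (s in 1:2) {
    n <- n + 1
    for (k in 1:3) loop <- loop - y[i, j, t, k, s] * log(p[i, j, t, k, s])
  }
  expect_equal(cross_entropy_loss(p, y), loop / n, tolerance = 1e-6)
})

test_that("seg loss combines CE and Dice with the configured weights", {
  # arithmetic with the default weights (1, 1.5)
  expect_equal(unified_loss(0.5, 0.3), 2.3)
  set.seed(3)
  cls <- array(sample(0:2, 4 * 4 * 1 * 2, replace = TRUE), c(4, 4, 1, 2))
  y <- onehot5(cls)
  p <- rand_probs(dim(y))
  w <- loss_weights()
  expect_equal(seg_loss(p, y, w),
               1 * cross_entropy_loss(p, y) + 1.5 * soft_dice_loss(p, y),
               tolerance = 1e-10)
  expect_equal(seg_loss(y, y, w), 0, tolerance = 1e-3)
  w0 <- loss_weights(lambda_dice = 1e-12)
  expect_equal(seg_loss(p, y, w0), cross_entropy_loss(p, y), tolerance = 1e-6)
  expect_error(loss_weights(lambda_ce = 0))
})

test_that("BCE matches closed forms and a loop oracle", {
  expect_equal(bce_loss(c(1, 0), c(1, 0)), 0, tolerance = 1e-5)
  expect_equal(bce_loss(rep(0.5, 8), rep(c(0, 1), 4)), log(2), tolerance = 1e-9)
  set.seed(4)
  p <- stats::runif(10, 0.05, 0.95)
  y <- stats::rbinom(10, 1, 0.5)
  loop <- mean(-y * log(p) - (1 - y) * log(1 - p))
  expect_equal(bce_loss(p, y), loop, tolerance = 1e-6)
  expect_error(bce_loss(p, y[1:3]), "mismatch")
})

test_that("MSE averages over samples and the 11 indices jointly", {
  t11 <- matrix(stats::runif(22), 11, 2)
  expect_equal(mse_loss(t11, t11), 0)
  p <- t11; p[3, 1] <- p[3, 1] + 0.1
  expect_equal(mse_loss(p, t11), 0.1^2 / 22, tolerance = 1e-12)
  one <- t11[, 1]; pone <- one; pone[5] <- pone[5] + 0.1
  expect_equal(mse_loss(pone, one), 0.1^2 / 11, tolerance = 1e-12)
  set.seed(5)
  pr <- matrix(stats::rnorm(44), 11, 4); tr <- matrix(stats::rnorm(44), 11, 4)
  loop <- 0
  for (s in 1:4) for (k in 1:11) loop <- loop + (pr[k, s] - tr[k, s])^2
  expect_equal(mse_loss(pr, tr), loop / 44, tolerance = 1e-9)
  expect_error(mse_loss(matrix(0, 7, 2), matrix(0, 7, 2)), "11 indices")
})

test_that("regression and unified losses are weighted sums", {
  t11 <- matrix(stats::runif(22), 11, 2)
  p <- t11 + 0.05
  pp <- c(0.8, 0.4); yy <- c(1, 0)
  expect_equal(reg_loss(p, t11, pp, yy),
               mse_loss(p, t11) + bce_loss(pp, yy), tolerance = 1e-12)
  expect_equal(reg_loss(t11, t11, c(1, 0), c(1, 0)), 0, tolerance = 1e-5)
  expect_equal(unified_loss(0, 0), 0)
  # monotone in the segmentation term
  expect_gt(unified_loss(0.6, 0.3), unified_loss(0.5, 0.3))
  # explicit lambda arithmetic: 4 * (1*0.2 + 1.5*0.4) would need seg parts;
  # the default-weight identity:
  w <- loss_weights()
  expect_equal(w$lambda_ce * 0.2 + w$lambda_dice * 0.4, 0.8)
})

test_that("losses are differentiable on the tape (finite differences)", {
  set.seed(6)
  cls <- array(sample(0:2, 3 * 3 * 1 * 2, replace = TRUE), c(3, 3, 1, 2))
  y <- onehot5(cls)
  logits <- array(stats::rnorm(prod(dim(y))), dim = dim(y))
  t11 <- matrix(stats::runif(22), 11, 2)
  pred0 <- matrix(stats::rnorm(22), 11, 2)
  phl0 <- matrix(stats::rnorm(4), 2, 2)
  phase_y <- c(1, 0)
  w <- loss_weights()

  loss_fn <- function(lg, pr, phl) {
    probs <- lvquant:::ad_softmax_c(lg)
    ls <- seg_loss(probs, lvquant:::ad_const(y), w)
    psys <- lvquant:::ad_row(lvquant:::ad_softmax_rows(phl), 2L)
    lr <- reg_loss(pr, lvquant:::ad_const(t11), psys, phase_y)
    unified_loss(ls, lr, w)
  }
  nl <- lvquant:::ad_param(logits)
  np <- lvquant:::ad_param(pred0)
  nph <- lvquant:::ad_param(phl0)
  loss <- loss_fn(nl, np, nph)
  lvquant:::ad_backward(loss)
  eps <- 1e-5
  for (probe in list(list(n = nl, x = logits, i = 7),
                     list(n = np, x = pred0, i = 3),
                     list(n = nph, x = phl0, i = 2))) {
    xp <- probe$x; xp[probe$i] <- xp[probe$i] + eps
    xm <- probe$x; xm[probe$i] <- xm[probe$i] - eps
    args <- list(nl = logits, np = pred0, nph = phl0)
    fd <- (lvquant:::ad_value(do.call(loss_fn, stats::setNames(lapply(
      c("nl", "np", "nph"), function(nm)
        lvquant:::ad_param(if (identical(probe$x, args[[nm]])) xp else args[[nm]])),
      c("lg", "pr", "phl")))) -
      lvquant:::ad_value(do.call(loss_fn, stats::setNames(lapply(
        c("nl", "np", "nph"), function(nm)
          lvquant:::ad_param(if (identical(probe$x, args[[nm]])) xm else args[[nm]])),
        c("lg", "pr", "phl"))))) / (2 * eps)
    expect_equal(probe$n$grad[probe$i], fd, tolerance = 1e-4)
  }
})
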