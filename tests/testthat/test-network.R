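# Architecture contracts of the two paths.

test_that("shape contract holds across configurable input sizes", {
  set.seed(1)
  for (hw in c(48L, 64L)) {
    m <- build_unified_model(test_seg_config(hw), test_reg_config())
    x <- array(rnorm(hw * hw * 5 * 2), c(hw, hw, 5, 1, 2))
    out <- lvquant:::ad_no_grad(forward_unified(m, x, training = FALSE))
    g <- hw %/% 16L
    expect_equal(dim(lvquant:::ad_value(out$seg$tokens)),
                 c(g * g * 5L, 16L, 2L))
    expect_equal(dim(lvquant:::ad_value(out$seg$logits)), c(hw, hw, 5L, 3L, 2L))
    expect_equal(dim(lvquant:::ad_value(out$reg$indices)), c(11L, 2L))
    expect_equal(dim(lvquant:::ad_value(out$reg$phase_logits)), c(2L, 2L))
  }
  expect_error(seg_config(image_hw = 50L), "divisible")
})

test_that("the slice axis is never pooled in the stem", {
  set.seed(2)
  path <- build_seg_path(test_seg_config(48L))
  x <- array(rnorm(48 * 48 * 5), c(48, 48, 5, 1, 1))
  out <- lvquant:::ad_no_grad(forward_seg(path, x, training = FALSE))
  gd <- dim(lvquant:::ad_value(out$grid))
  expect_equal(gd[3], 5L)                       # slices preserved to the grid
  expect_equal(dim(lvquant:::ad_value(out$f_full))[3], 5L)
})

test_that("per-pixel class probabilities sum to one", {
  set.seed(3)
  path <- build_seg_path(test_seg_config(48L))
  x <- array(rnorm(48 * 48 * 5), c(48, 48, 5, 1, 1))
  out <- lvquant:::ad_no_grad(forward_seg(path, x, training = FALSE))
  probs <- lvquant:::ad_value(lvquant:::ad_softmax_c(out$logits))
  sums <- probs[, , , 1, ] + probs[, , , 2, ] + probs[, , , 3, ]
  expect_equal(range(sums), c(1, 1), tolerance = 1e-12)
})

test_that("attention rows are normalized and zero depth is identity", {
  set.seed(4)
  tok <- array(rnorm(10 * 8 * 2), c(10, 8, 2))
  mats <- replicate(4, matrix(rnorm(64) * 0.3, 8, 8), simplify = FALSE)
  # softmax normalisation inside attention: reconstruct one head's rows
  x <- tok[, , 1]
  Q <- tcrossprod(x, mats[[1]]); K <- tcrossprod(x, mats[[2]])
  S <- tcrossprod(Q[, 1:4], K[, 1:4]) / sqrt(4)
  A <- exp(S - apply(S, 1, max)); A <- A / rowSums(A)
  expect_equal(unname(rowSums(A)), rep(1, 10), tolerance = 1e-12)

  # zero transformer depth: tokens pass through with only the positional
  # embedding added
  cfg <- test_seg_config(48L); cfg$depth <- 0L
  path <- build_seg_path(cfg)
  xin <- array(rnorm(48 * 48 * 5), c(48, 48, 5, 1, 1))
  out <- lvquant:::ad_no_grad(forward_seg(path, xin, training = FALSE))
  grid <- lvquant:::ad_value(out$grid)
  toks <- lvquant:::ad_value(out$tokens)
  manual <- array(grid, dim = c(45, 16, 1))[, , 1] + lvquant:::ad_value(path$pos)
  expect_equal(toks[, , 1], manual, tolerance = 1e-12)
})

test_that("an untrained net already covers all three classes on random input", {
  set.seed(5)
  path <- build_seg_path(test_seg_config(48L))
  x <- array(rnorm(48 * 48 * 5 * 2), c(48, 48, 5, 1, 2))
  logits <- lvquant:::ad_value(lvquant:::ad_no_grad(
    forward_seg(path, x, training = FALSE))$logits)
  lab <- apply(logits, c(1, 2, 3, 5), which.max)
  expect_setequal(unique(as.integer(lab)), 1:3)
})

test_that("RRA blocks preserve shape and their SE gates stay in (0,1)", {
  set.seed(6)
  bl <- lvquant:::build_rra_block(4L, 4L, se_reduction = 2L, recurrence = 2L)
  x <- array(rnorm(8 * 8 * 3 * 4 * 2), c(8, 8, 3, 4, 2))
  out <- lvquant:::ad_no_grad(lvquant:::fwd_rra_block(bl, x, training = TRUE))
  expect_equal(dim(lvquant:::ad_value(out)), dim(x))
  gate <- lvquant:::ad_no_grad(lvquant:::fwd_se(bl$se, lvquant:::as_ad(x)))
  s <- lvquant:::ad_value(gate) / x
  s <- s[is.finite(s)]
  expect_true(all(s > 0 & s < 1))
})

test_that("spatio-temporal blocks implement 5 -> 3 -> 1 slice collapse", {
  set.seed(7)
  b1 <- lvquant:::build_st_block(4L, 6L)
  b2 <- lvquant:::build_st_block(6L, 8L)
  x <- array(rnorm(40 * 40 * 5 * 4), c(40, 40, 5, 4, 1))
  h1 <- lvquant:::ad_no_grad(lvquant:::fwd_st_block(b1, x, training = TRUE))
  expect_equal(dim(lvquant:::ad_value(h1)), c(20, 20, 3, 6, 1))
  h2 <- lvquant:::ad_no_grad(lvquant:::fwd_st_block(b2, h1, training = TRUE))
  expect_equal(dim(lvquant:::ad_value(h2)), c(10, 10, 1, 8, 1))
  expect_error(lvquant:::fwd_st_block(b2, h2, training = TRUE), "3 slices")
})

test_that("the central output slice sees all five input slices", {
  # temporal receptive field through two unpadded 3-tap convolutions
  set.seed(8)
  m <- build_unified_model(test_seg_config(48L),
                           reg_config(channels = c(2L, 4L, 8L),
                                      recurrence = 1L, phase_hidden = 12L,
                                      fuse = FALSE))
  x <- array(rnorm(48 * 48 * 5), c(48, 48, 5, 1, 1))
  base <- lvquant:::ad_value(lvquant:::ad_no_grad(
    forward_reg(m$reg, x, NULL, training = FALSE))$indices)
  for (t in 1:5) {
    xp <- x
    xp[, , t, , ] <- xp[, , t, , ] + 3
    pert <- lvquant:::ad_value(lvquant:::ad_no_grad(
      forward_reg(m$reg, xp, NULL, training = FALSE))$indices)
    expect_gt(max(abs(pert - base)), 0)
  }
})

test_that("segmentation-feature fusion is live", {
  set.seed(9)
  m <- build_unified_model(test_seg_config(48L), test_reg_config())
  x <- array(rnorm(48 * 48 * 5), c(48, 48, 5, 1, 1))
  seg_out <- lvquant:::ad_no_grad(forward_seg(m$seg, x, training = FALSE))
  r1 <- lvquant:::ad_value(lvquant:::ad_no_grad(
    forward_reg(m$reg, x, seg_out, training = FALSE))$indices)
  # zero the fused features: output must change
  zf <- seg_out
  zf$f_full <- lvquant:::ad_const(lvquant:::ad_value(seg_out$f_full) * 0)
  zf$f_half <- lvquant:::ad_const(lvquant:::ad_value(seg_out$f_half) * 0)
  r2 <- lvquant:::ad_value(lvquant:::ad_no_grad(
    forward_reg(m$reg, x, zf, training = FALSE))$indices)
  expect_gt(max(abs(r1 - r2)), 1e-8)

  # evaluation forward is deterministic
  r3 <- lvquant:::ad_value(lvquant:::ad_no_grad(
    forward_reg(m$reg, x, seg_out, training = FALSE))$indices)
  expect_identical(r1, r3)
})

test_that("parameter counts are finite and reported", {
  m <- build_unified_model(test_seg_config(48L), test_reg_config())
  n <- n_parameters(m$seg) + n_parameters(m$reg)
  expect_true(is.finite(n) && n > 1000)
})
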