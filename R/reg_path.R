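# Regression path: spatio-temporal convolution with recurrent-residual
# attention blocks and squeeze-and-excitation fusion of segmentation
# decoder features.
#
# The raw 5-frame window passes through RRA blocks (two recurrent-residual
# conv units plus SE channel attention) and two spatio-temporal blocks
# (an unpadded 3-tap temporal conv followed by a padded 3x3 spatial conv,
# batch norm, ReLU and 1x2x2 max pooling), collapsing the 5 slices to the
# central one (5 -> 3 -> 1) while halving the spatial grid twice. Decoder
# features from the segmentation path are fused at matching scales by
# channel concatenation + SE + 1x1x1 projection. Two heads read the final
# map: a shallow convolutional regressor for the 11 indices and a 360-unit
# perceptron for the 2 phase logits of the centre frame.

#' Regression path configuration
#'
#' @param channels widths after the first RRA block, the first
#'   spatio-temporal block and the second spatio-temporal block
#' @param recurrence recurrence steps of each recurrent-residual conv unit
#' @param se_reduction squeeze-and-excitation reduction ratio
#' @param phase_hidden width of the phase perceptron hidden layer
#' @param n_indices regression output arity
#' @param fuse enable fusion of segmentation decoder features
#' @param stop_gradient cut the gradient from the regression loss into the
#'   segmentation path through the fused features
#' @param sigmoid_clamp squash index outputs through a sigmoid (off by
#'   default; trained targets already lie in `[0, 1)`)
#' @return a `lvq_reg_config` list
#' @export
reg_config <- function(channels = c(32L, 64L, 96L), recurrence = 2L,
                       se_reduction = 8L, phase_hidden = 360L,
                       n_indices = 11L, fuse = TRUE, stop_gradient = FALSE,
                       sigmoid_clamp = FALSE) {
  structure(list(channels = channels, recurrence = recurrence,
                 se_reduction = se_reduction, phase_hidden = phase_hidden,
                 n_indices = n_indices, fuse = fuse,
                 stop_gradient = stop_gradient,
                 sigmoid_clamp = sigmoid_clamp),
            class = "lvq_reg_config")
}

build_rra_unit <- function(cin, cout) {
  list(conv = layer_conv3d(3, 3, 3, cout, cout), bn = layer_batchnorm(cout),
       proj = if (cin != cout) layer_conv3d(1, 1, 1, cin, cout))
}

build_rra_block <- function(cin, cout, se_reduction, recurrence) {
  list(unit1 = build_rra_unit(cin, cout),
       unit2 = build_rra_unit(cout, cout),
       shortcut = layer_conv3d(1, 1, 1, cin, cout),
       se = layer_se(cout, se_reduction),
       recurrence = recurrence)
}

build_st_block <- function(cin, cout) {
  list(temporal = layer_conv3d(1, 1, 3, cin, cout),
       spatial = layer_conv3d(3, 3, 1, cout, cout),
       bn_t = layer_batchnorm(cout), bn_s = layer_batchnorm(cout))
}

build_fuse <- function(reg_ch, seg_ch, se_reduction) {
  list(se = layer_se(reg_ch + seg_ch, se_reduction),
       proj = layer_conv3d(1, 1, 1, reg_ch + seg_ch, reg_ch))
}

#' Build the regression path
#' @param cfg a [reg_config()]
#' @param seg_cfg the [seg_config()] of the companion segmentation path
#'   (decoder channel widths size the fusion layers)
#' @return a parameter structure consumed by [forward_reg()]
#' @export
build_reg_path <- function(cfg, seg_cfg) {
  ch <- cfg$channels
  dc <- seg_cfg$decoder_channels
  list(cfg = cfg,
       rra1 = build_rra_block(seg_cfg$in_channels, ch[1], cfg$se_reduction,
                              cfg$recurrence),
       fuse1 = if (cfg$fuse) build_fuse(ch[1], dc[4], cfg$se_reduction),
       st1 = build_st_block(ch[1], ch[2]),
       rra2 = build_rra_block(ch[2], ch[2], cfg$se_reduction, cfg$recurrence),
       fuse2 = if (cfg$fuse) build_fuse(ch[2], dc[3], cfg$se_reduction),
       st2 = build_st_block(ch[2], ch[3]),
       idx_conv = layer_conv3d(1, 1, 1, ch[3], ch[3]),
       idx_bn = layer_batchnorm(ch[3]),
       idx_out = layer_dense(ch[3], cfg$n_indices),
       phase_bn = layer_batchnorm(ch[3]),
       phase_fc1 = layer_dense(ch[3], cfg$phase_hidden),
       phase_fc2 = layer_dense(cfg$phase_hidden, 2L))
}

# One recurrent-residual conv unit: the input is projected to the unit
# width, then the same convolution is applied `recurrence` times, each
# pass re-injecting the unit input.
fwd_rra_unit <- function(u, x, recurrence, training) {
  xin <- if (is.null(u$proj)) x else fwd_conv(u$proj, x)
  h <- ad_relu(fwd_bn(u$bn, fwd_conv(u$conv, xin, pad = c(1, 1, 1)), training))
  if (recurrence > 1) {
    for (k in seq_len(recurrence - 1)) {
      h <- ad_relu(fwd_bn(u$bn, fwd_conv(u$conv, ad_add(xin, h),
                                         pad = c(1, 1, 1)), training))
    }
  }
  h
}

fwd_rra_block <- function(bl, x, training) {
  h <- fwd_rra_unit(bl$unit1, x, bl$recurrence, training)
  h <- fwd_rra_unit(bl$unit2, h, bl$recurrence, training)
  h <- ad_add(h, fwd_conv(bl$shortcut, x))
  fwd_se(bl$se, h)
}

fwd_st_block <- function(bl, x, training) {
  if (dim(as_ad(x)$v)[3] < 3L)
    stop("spatio-temporal block needs at least 3 slices")
  h <- fwd_conv(bl$temporal, x)                     # unpadded: T -> T-2
  h <- ad_relu(fwd_bn(bl$bn_t, h, training))
  h <- fwd_conv(bl$spatial, h, pad = c(1, 1, 0))
  h <- ad_relu(fwd_bn(bl$bn_s, h, training))
  ad_maxpool(h, c(2, 2, 1))
}

fwd_fuse <- function(fu, reg_f, seg_f, stop_gradient) {
  if (stop_gradient) seg_f <- ad_const(ad_value(seg_f))
  h <- ad_concat_c(reg_f, seg_f)
  h <- fwd_se(fu$se, h)
  fwd_conv(fu$proj, h)
}

#' Forward pass of the regression path
#'
#' @param path structure from [build_reg_path()]
#' @param x input window tensor `(H, W, slices, 1, batch)`
#' @param seg_out output list of [forward_seg()] on the same window (only
#'   needed when fusion is enabled)
#' @param training training mode (batch-norm statistics)
#' @return list: `indices` (`n_indices x batch`), `phase_logits`
#'   (`2 x batch`)
#' @export
forward_reg <- function(path, x, seg_out = NULL, training = TRUE) {
  cfg <- path$cfg
  x <- as_ad(x)
  f <- fwd_rra_block(path$rra1, x, training)
  if (cfg$fuse) {
    if (is.null(seg_out)) stop("fusion enabled but no segmentation features given")
    f <- fwd_fuse(path$fuse1, f, seg_out$f_full, cfg$stop_gradient)
  }
  f <- fwd_st_block(path$st1, f, training)          # T 5->3, HW halved
  f <- fwd_rra_block(path$rra2, f, training)
  if (cfg$fuse) {
    mid <- ad_slice_t(seg_out$f_half, 2:4)          # centre 3 slices
    f <- fwd_fuse(path$fuse2, f, mid, cfg$stop_gradient)
  }
  f <- fwd_st_block(path$st2, f, training)          # T 3->1, HW halved

  # pooled features are standardized across the batch before each head so
  # the heads see O(1) between-sample variance
  pool_bn <- function(x, bn) {
    d <- dim(ad_value(as_ad(x)))
    h <- ad_reshape(x, c(1L, 1L, 1L, d[1], d[2]))
    h <- fwd_bn(bn, h, training)
    ad_reshape(h, d)
  }
  hi <- ad_relu(fwd_conv(path$idx_conv, f))
  gi <- pool_bn(ad_global_avgpool(hi), path$idx_bn)
  idx <- ad_dense(gi, path$idx_out$w, path$idx_out$b)
  if (cfg$sigmoid_clamp) idx <- ad_sigmoid(idx)
  g <- pool_bn(ad_global_avgpool(f), path$phase_bn)
  ph <- ad_relu(ad_dense(g, path$phase_fc1$w, path$phase_fc1$b))
  ph <- ad_dense(ph, path$phase_fc2$w, path$phase_fc2$b)
  list(indices = idx, phase_logits = ph)
}
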