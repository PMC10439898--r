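# Segmentation path: U-Net-like 3D hybrid CNN-Transformer.
#
# A residual 3D-conv stem with three spatial downsampling stages (group
# norm, randomized leaky ReLU, 1x2x2 max pooling; the slice axis is never
# pooled) feeds a patch-embedding convolution of spatial stride 2 that
# produces the token grid (5x5x5 cells of `hidden` channels for an 80x80,
# 5-slice window, i.e. 125 tokens). A pre-norm multi-head self-attention
# encoder processes the tokens; a cascaded transposed-convolution decoder
# with stem skips restores full resolution and emits 3-class logits for
# all 5 slices. Intermediate decoder features at the 1/1 and 1/2 scales
# are exposed for the regression path.

#' Segmentation path configuration
#'
#' @param in_channels input channels (cine MRI: 1)
#' @param n_classes segmentation classes (background, cavity, myocardium)
#' @param stem_channels channel widths of the three stem stages
#' @param hidden transformer token width (matches the embedded feature
#'   channels)
#' @param depth,heads,mlp_ratio transformer encoder depth, attention heads
#'   and MLP expansion ratio
#' @param decoder_channels widths of the four decoder stages
#' @param groups target group count for group normalization
#' @param image_hw spatial side length of the input window (must be
#'   divisible by 16)
#' @param slices temporal window width
#' @param rrelu_range slope range of the randomized leaky rectifier
#' @return a `lvq_seg_config` list
#' @export
seg_config <- function(in_channels = 1L, n_classes = 3L,
                       stem_channels = c(32L, 64L, 128L), hidden = 256L,
                       depth = 4L, heads = 8L, mlp_ratio = 4,
                       decoder_channels = c(128L, 64L, 32L, 16L),
                       groups = 8L, image_hw = 80L, slices = 5L,
                       rrelu_range = c(1 / 8, 1 / 3)) {
  if (image_hw %% 16L != 0L)
    stop("image_hw must be divisible by the total downsampling factor 16")
  if (hidden %% heads != 0L) stop("hidden must be divisible by heads")
  structure(list(in_channels = in_channels, n_classes = n_classes,
                 stem_channels = stem_channels, hidden = hidden,
                 depth = depth, heads = heads, mlp_ratio = mlp_ratio,
                 decoder_channels = decoder_channels, groups = groups,
                 image_hw = image_hw, slices = slices,
                 rrelu_range = rrelu_range),
            class = "lvq_seg_config")
}

build_stem_stage <- function(cin, cout, groups) {
  list(conv_a = layer_conv3d(3, 3, 3, cin, cout),
       gn_a = layer_norm_affine(cout),
       conv_b = layer_conv3d(3, 3, 3, cout, cout),
       gn_b = layer_norm_affine(cout),
       shortcut = layer_conv3d(1, 1, 1, cin, cout),
       groups = gn_groups(cout, groups))
}

build_transformer_block <- function(D, mlp_ratio) {
  hiddenD <- round(D * mlp_ratio)
  list(ln1 = layer_norm_affine(D),
       wq = ad_param(he_init(c(D, D), D)), bq = ad_param(numeric(D)),
       wk = ad_param(he_init(c(D, D), D)), bk = ad_param(numeric(D)),
       wv = ad_param(he_init(c(D, D), D)), bv = ad_param(numeric(D)),
       wo = ad_param(he_init(c(D, D), D)), bo = ad_param(numeric(D)),
       ln2 = layer_norm_affine(D),
       mlp1 = layer_dense(D, hiddenD), mlp2 = layer_dense(hiddenD, D))
}

build_decoder_stage <- function(cin_up, cout, skip_ch, groups) {
  list(up = layer_convt3d(2, 2, 1, cin_up, cout),
       conv = layer_conv3d(3, 3, 3, cout + skip_ch, cout),
       gn = layer_norm_affine(cout),
       groups = gn_groups(cout, groups))
}

#' Build the segmentation path
#' @param cfg a [seg_config()]
#' @return a parameter structure consumed by [forward_seg()]
#' @export
build_seg_path <- function(cfg) {
  sc <- cfg$stem_channels
  dc <- cfg$decoder_channels
  n_tokens <- (cfg$image_hw %/% 16L)^2 * cfg$slices
  list(cfg = cfg,
       stem = list(
         build_stem_stage(cfg$in_channels, sc[1], cfg$groups),
         build_stem_stage(sc[1], sc[2], cfg$groups),
         build_stem_stage(sc[2], sc[3], cfg$groups)),
       embed = layer_conv3d(2, 2, 1, sc[3], cfg$hidden),
       pos = ad_param(array(stats::rnorm(n_tokens * cfg$hidden, 0, 0.02),
                            c(n_tokens, cfg$hidden))),
       blocks = lapply(seq_len(cfg$depth), function(i)
         build_transformer_block(cfg$hidden, cfg$mlp_ratio)),
       decoder = list(
         build_decoder_stage(cfg$hidden, dc[1], 0L, cfg$groups),
         build_decoder_stage(dc[1], dc[2], sc[3], cfg$groups),
         build_decoder_stage(dc[2], dc[3], sc[2], cfg$groups),
         build_decoder_stage(dc[3], dc[4], sc[1], cfg$groups)),
       head = layer_conv3d(1, 1, 1, dc[4], cfg$n_classes))
}

fwd_stem_stage <- function(st, x, training, rrange) {
  h <- fwd_conv(st$conv_a, x, pad = c(1, 1, 1))
  h <- ad_groupnorm(h, st$gn_a$gamma, st$gn_a$beta, st$groups)
  h <- fwd_rrelu(h, rrange, training)
  h <- fwd_conv(st$conv_b, h, pad = c(1, 1, 1))
  h <- ad_groupnorm(h, st$gn_b$gamma, st$gn_b$beta, st$groups)
  h <- ad_add(h, fwd_conv(st$shortcut, x))
  fwd_rrelu(h, rrange, training)
}

fwd_transformer_block <- function(bl, x, heads) {
  h <- ad_layernorm(x, bl$ln1$gamma, bl$ln1$beta)
  h <- ad_mha(h, bl$wq, bl$wk, bl$wv, bl$wo, bl$bq, bl$bk, bl$bv, bl$bo, heads)
  x <- ad_add(x, h)
  h <- ad_layernorm(x, bl$ln2$gamma, bl$ln2$beta)
  h <- ad_dense_tokens(h, bl$mlp1$w, bl$mlp1$b)
  h <- ad_gelu(h)
  h <- ad_dense_tokens(h, bl$mlp2$w, bl$mlp2$b)
  ad_add(x, h)
}

#' Forward pass of the segmentation path
#'
#' @param path structure from [build_seg_path()]
#' @param x input window tensor, dim `(H, W, slices, in_channels, batch)`
#' @param training training mode (randomized activations)
#' @return list: `logits` (`H x W x slices x n_classes x batch`), decoder
#'   features `f_full` and `f_half`, the `tokens` sequence
#'   (`L x hidden x batch`) and the embedded `grid`
#' @export
forward_seg <- function(path, x, training = TRUE) {
  cfg <- path$cfg
  x <- as_ad(x)
  d <- dim(x$v)
  if (d[1] %% 16L != 0L || d[2] %% 16L != 0L)
    stop("input spatial size must be divisible by 16")
  rr <- cfg$rrelu_range
  skips <- vector("list", 3L)
  h <- x
  for (s in 1:3) {
    h <- fwd_stem_stage(path$stem[[s]], h, training, rr)
    skips[[s]] <- h                       # pre-pooling skip
    h <- ad_maxpool(h, c(2, 2, 1))
  }
  grid <- fwd_conv(path$embed, h, stride = c(2, 2, 1))  # (g, g, T, hidden, N)
  gd <- dim(grid$v)
  L <- gd[1] * gd[2] * gd[3]
  tokens <- ad_reshape(grid, c(L, gd[4], gd[5]))
  tokens <- ad_add_posemb(tokens, path$pos)
  for (bl in path$blocks)
    tokens <- fwd_transformer_block(bl, tokens, cfg$heads)
  h <- ad_reshape(tokens, gd)

  dec <- path$decoder
  up1 <- fwd_convt(dec[[1]]$up, h)
  f <- fwd_conv(dec[[1]]$conv, up1, pad = c(1, 1, 1))
  f <- ad_relu(ad_groupnorm(f, dec[[1]]$gn$gamma, dec[[1]]$gn$beta, dec[[1]]$groups))
  for (s in 2:4) {
    up <- fwd_convt(dec[[s]]$up, f)
    cat_in <- ad_concat_c(up, skips[[5 - s]])
    f <- fwd_conv(dec[[s]]$conv, cat_in, pad = c(1, 1, 1))
    f <- ad_relu(ad_groupnorm(f, dec[[s]]$gn$gamma, dec[[s]]$gn$beta, dec[[s]]$groups))
    if (s == 3) f_half <- f
  }
  logits <- fwd_conv(path$head, f)
  list(logits = logits, f_full = f, f_half = f_half,
       tokens = tokens, grid = grid)
}
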