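# Joint multi-task objective.
#
# Segmentation: class-averaged soft Dice plus pixel-mean cross-entropy,
# combined as lambda_ce * CE + lambda_dice * Dice. Regression: MSE over the
# 11 indices plus binary cross-entropy on the phase probability. The
# unified loss weights the segmentation path above the regression path
# (4 : 1 by default). Every function accepts plain arrays or tape nodes;
# plain inputs return a plain scalar.

#' Loss weights of the joint objective
#'
#' @param lambda_ce,lambda_dice weights of cross-entropy and Dice inside
#'   the segmentation loss (defaults 1 and 1.5)
#' @param lambda_seg,lambda_reg weights of the segmentation and regression
#'   paths in the unified loss (defaults 4 and 1)
#' @return a `lvq_loss_weights` list
#' @export
loss_weights <- function(lambda_ce = 1, lambda_dice = 1.5,
                         lambda_seg = 4, lambda_reg = 1) {
  stopifnot(lambda_ce > 0, lambda_dice > 0, lambda_seg > 0, lambda_reg > 0)
  structure(list(lambda_ce = lambda_ce, lambda_dice = lambda_dice,
                 lambda_seg = lambda_seg, lambda_reg = lambda_reg),
            class = "lvq_loss_weights")
}

# Return a plain scalar when all original inputs were plain.
unwrap_if_plain <- function(node, ...) {
  if (any(vapply(list(...), inherits, logical(1), "ad_node"))) node
  else as.numeric(ad_value(node))
}

# One-hot encode an integer class field (H,W,T,N) -> (H,W,T,K,N).
one_hot_masks <- function(masks, n_classes = 3L) {
  d <- dim(masks)
  if (length(d) == 3L) { d <- c(d, 1L); dim(masks) <- d }
  out <- array(0, dim = c(d[1:3], n_classes, d[4]))
  for (k in seq_len(n_classes) - 1L) {
    sel <- masks == k
    out[, , , k + 1L, ][sel] <- 1
  }
  out
}

#' Class-averaged soft Dice loss
#'
#' `1 - (2/K) * sum_k [ (sum_i y ... + eps) / (sum_i (y + p) + eps) ]` with
#' soft per-class probability overlaps, smoothing `eps` in numerator and
#' denominator; value in `[0, 1]`.
#'
#' @param probs per-class probabilities, dim `(H, W, T, K, N)` (array or
#'   tape node), summing to 1 over classes
#' @param target one-hot class maps of the same shape
#' @param eps smoothing constant
#' @return scalar loss (tape node if any input is one)
#' @export
soft_dice_loss <- function(probs, target, eps = 1e-5) {
  p <- as_ad(probs); y <- as_ad(target)
  if (!identical(dim(p$v), dim(y$v))) stop("probs/target shape mismatch")
  K <- dim(p$v)[4]
  inter <- ad_sum_class(ad_mul(p, y))
  tot <- ad_sum_class(ad_add(p, y))
  frac <- ad_div(ad_add_const(ad_scale(inter, 2), eps), ad_add_const(tot, eps))
  out <- ad_add_const(ad_scale(ad_sum(frac), -1 / K), 1)
  unwrap_if_plain(out, probs, target)
}

#' Pixel-averaged cross-entropy loss
#'
#' `-(1/N) sum_i sum_c y_ic log p_ic` over all pixels, slices and batch
#' samples, with a probability floor for numerical safety.
#'
#' @inheritParams soft_dice_loss
#' @param floor probability floor inside the logarithm
#' @return scalar loss (tape node if any input is one)
#' @export
cross_entropy_loss <- function(probs, target, floor = 1e-12) {
  p <- as_ad(probs); y <- as_ad(target)
  if (!identical(dim(p$v), dim(y$v))) stop("probs/target shape mismatch")
  n_pix <- prod(dim(p$v)[-4])
  out <- ad_scale(ad_sum(ad_mul(y, ad_log(p, floor))), -1 / n_pix)
  unwrap_if_plain(out, probs, target)
}

#' Segmentation-path loss
#'
#' `lambda_ce * CE + lambda_dice * Dice`.
#' @inheritParams soft_dice_loss
#' @param weights a [loss_weights()]
#' @return scalar loss (tape node if any input is one)
#' @export
seg_loss <- function(probs, target, weights = loss_weights()) {
  ce <- cross_entropy_loss(probs, target)
  di <- soft_dice_loss(probs, target)
  if (inherits(ce, "ad_node"))
    ad_add(ad_scale(ce, weights$lambda_ce), ad_scale(di, weights$lambda_dice))
  else weights$lambda_ce * ce + weights$lambda_dice * di
}

#' Binary cross-entropy on the phase probability
#'
#' Mean over the batch of `-y log p - (1-y) log(1-p)` with probabilities
#' floored away from 0 and 1.
#'
#' @param phase_prob predicted probability of systole per sample (vector
#'   or tape node)
#' @param phase_target binary labels (1 = systole)
#' @param floor probability floor
#' @return scalar loss (tape node if any input is one)
#' @export
bce_loss <- function(phase_prob, phase_target, floor = 1e-7) {
  p <- as_ad(phase_prob)
  y <- as.numeric(ad_value(as_ad(phase_target)))
  if (length(p$v) != length(y)) stop("phase prediction/target length mismatch")
  n <- length(y)
  t1 <- ad_mul(ad_const(y), ad_log(p, floor))
  t2 <- ad_mul(ad_const(1 - y), ad_log(ad_sub(1, p), floor))
  out <- ad_scale(ad_add(t1, t2), -1)
  out <- ad_scale(ad_sum(out), 1 / n)
  unwrap_if_plain(out, phase_prob, phase_target)
}

#' Mean squared error over the 11 indices
#'
#' Mean of squared differences jointly over indices and batch samples, so
#' the loss scale does not depend on the index count.
#'
#' @param pred_indices predicted indices, `11 x batch` matrix (or vector
#'   of 11) or tape node
#' @param target_indices matching ground-truth indices
#' @param n_indices expected index count
#' @return scalar loss (tape node if any input is one)
#' @export
mse_loss <- function(pred_indices, target_indices, n_indices = 11L) {
  p <- as_ad(pred_indices); y <- as_ad(target_indices)
  pv <- p$v; yv <- ad_value(y)
  if (is.null(dim(pv))) dim(pv) <- c(length(pv), 1L)
  if ((dim(pv)[1] %||% length(pv)) != n_indices ||
      length(pv) != length(yv))
    stop("expected ", n_indices, " indices per sample in both arguments")
  out <- ad_mean(ad_pow2(ad_sub(p, y)))
  unwrap_if_plain(out, pred_indices, target_indices)
}

#' Regression-path loss
#'
#' `MSE(indices) + BCE(phase)`, unit weights.
#' @inheritParams mse_loss
#' @inheritParams bce_loss
#' @return scalar loss (tape node if any input is one)
#' @export
reg_loss <- function(pred_indices, target_indices, phase_prob, phase_target) {
  m <- mse_loss(pred_indices, target_indices)
  b <- bce_loss(phase_prob, phase_target)
  if (inherits(m, "ad_node") || inherits(b, "ad_node"))
    ad_add(as_ad(m), as_ad(b))
  else m + b
}

#' Unified multi-task loss
#'
#' `lambda_seg * L_seg + lambda_reg * L_reg`.
#' @param seg_term scalar segmentation-path loss (number or tape node)
#' @param reg_term scalar regression-path loss
#' @param weights a [loss_weights()]
#' @return scalar loss (tape node if any input is one)
#' @export
unified_loss <- function(seg_term, reg_term, weights = loss_weights()) {
  if (inherits(seg_term, "ad_node") || inherits(reg_term, "ad_node"))
    ad_add(ad_scale(as_ad(seg_term), weights$lambda_seg),
           ad_scale(as_ad(reg_term), weights$lambda_reg))
  else weights$lambda_seg * seg_term + weights$lambda_reg * reg_term
}
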