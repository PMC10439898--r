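# Evaluation metrics: per-class Dice and Hausdorff distance for
# segmentation; per-index MAE and Pearson correlation plus the phase error
# rate for quantification; report assembly with frame-weighted pooling.

#' Dice coefficient of two regions
#'
#' `2|A intersect B| / (|A| + |B|)`; two empty regions count as perfect
#' agreement (1), an empty versus a non-empty region as 0.
#'
#' @param a,b logical masks on the same grid
#' @return scalar in `[0, 1]`
#' @export
dice_coef <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks must share a grid")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

# Boundary pixels: region pixels with at least one differing 4-neighbour
# (image border counts as differing).
boundary_points <- function(mask) {
  mask <- mask != 0
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- mask
  inner <- pad[2:(H + 1L), 2:(W + 1L)]
  nb <- pad[1:H, 2:(W + 1L)] & pad[3:(H + 2L), 2:(W + 1L)] &
    pad[2:(H + 1L), 1:W] & pad[2:(H + 1L), 3:(W + 2L)]
  which(inner & !nb, arr.ind = TRUE) - 1L  # 0-based coordinates
}

#' Symmetric Hausdorff distance between two regions
#'
#' Boundaries are extracted as pixels with a differing 4-neighbour; the
#' distance is `max[h(A,B), h(B,A)]` with
#' `h(A,B) = max_a min_b ||a - b||` (Euclidean, pixels; multiply by the
#' pixel spacing for mm).
#'
#' @param a,b logical masks on the same grid, both non-empty
#' @return distance in pixels
#' @export
hausdorff <- function(a, b) {
  as_points <- function(x) {
    if (is.matrix(x) && !is.logical(x) && ncol(x) == 2L) x
    else boundary_points(x)
  }
  if (is.logical(a) && is.logical(b) && !identical(dim(a), dim(b)))
    stop("masks must share a grid")
  pa <- as_points(a); pb <- as_points(b)
  if (nrow(pa) == 0L || nrow(pb) == 0L)
    stop("degenerate mask: empty boundary")
  d2 <- outer(pa[, 1], pb[, 1], `-`)^2 + outer(pa[, 2], pb[, 2], `-`)^2
  sqrt(max(max(apply(d2, 1L, min)), max(apply(d2, 2L, min))))
}

#' Mean absolute error between two series
#' @param pred,target equal-length numeric vectors
#' @return scalar
#' @export
mae <- function(pred, target) {
  if (length(pred) != length(target)) stop("series length mismatch")
  mean(abs(pred - target))
}

#' Pearson correlation coefficient
#'
#' Covariance normalized by the product of the two standard deviations;
#' each series is centred by its own mean.
#'
#' @param pred,target equal-length numeric vectors, both non-constant
#' @return scalar in `[-1, 1]`
#' @export
pcc <- function(pred, target) {
  if (length(pred) != length(target)) stop("series length mismatch")
  if (length(pred) < 2L) stop("need at least two observations")
  cp <- pred - mean(pred); ct <- target - mean(target)
  den <- sqrt(sum(cp^2) * sum(ct^2))
  if (den == 0) stop("undefined correlation: constant series")
  sum(cp * ct) / den
}

#' Phase misclassification rate
#' @param pred,target equal-length binary label vectors
#' @return fraction of mismatching frames
#' @export
phase_error_rate <- function(pred, target) {
  if (length(pred) != length(target)) stop("series length mismatch")
  mean(pred != target)
}

#' Evaluate predictions against ground truth
#'
#' Pools per-frame results across subjects: Dice and Hausdorff are
#' frame-weighted means per class, MAE is the frame-weighted mean per
#' index (normalized units, plus physical units via the spacing), PCC is
#' computed on the pooled per-index series, and the phase error rate over
#' all frames.
#'
#' @param predictions list of per-subject predictions (each with `masks`,
#'   an `H x W x n_frames` class array, and `indices`, a tibble in the
#'   `indices.csv` schema); masks may be `NULL` for regression-only
#'   evaluation
#' @param truth list of matching `lvq_subject` objects
#' @param spacing pixel spacing mm/pixel (defaults to the subjects')
#' @return an `lvq_metric_report`
#' @export
evaluate <- function(predictions, truth, spacing = NULL) {
  stopifnot(length(predictions) == length(truth))
  if (is.null(spacing))
    spacing <- truth[[1]]$spacing %||% lvq_default_spacing
  class_names <- c(background = 0L, cavity = 1L, myocardium = 2L)
  dice_acc <- matrix(NA_real_, 0L, 3L)
  hd_acc <- matrix(NA_real_, 0L, 3L)
  pred_idx <- list(); true_idx <- list()
  for (s in seq_along(predictions)) {
    p <- predictions[[s]]; t <- truth[[s]]
    pred_idx[[s]] <- p$indices
    true_idx[[s]] <- t$indices
    if (is.null(p$masks)) next
    n <- dim(p$masks)[3]
    for (f in seq_len(n)) {
      dice_acc <- rbind(dice_acc, vapply(class_names, function(k)
        dice_coef(p$masks[, , f] == k, t$masks[, , f] == k), numeric(1)))
      hd_acc <- rbind(hd_acc, vapply(class_names, function(k) {
        a <- p$masks[, , f] == k; b <- t$masks[, , f] == k
        if (sum(a) == 0L || sum(b) == 0L) return(NA_real_)
        hausdorff(a, b)
      }, numeric(1)))
    }
  }
  pred_tab <- dplyr::bind_rows(pred_idx)
  true_tab <- dplyr::bind_rows(true_idx)
  H <- dim(truth[[1]]$masks %||% truth[[1]]$images)[1]
  phys <- c(rep(H * H * spacing^2, 2), rep(H * spacing, 9))  # mm^2 / mm
  mae_n <- vapply(lvq_index_names, function(j)
    mae(pred_tab[[j]], true_tab[[j]]), numeric(1))
  pcc_v <- vapply(lvq_index_names, function(j)
    pcc(pred_tab[[j]], true_tab[[j]]), numeric(1))
  report <- list(
    dice = if (nrow(dice_acc)) stats::setNames(colMeans(dice_acc),
                                               names(class_names)),
    hausdorff_px = if (nrow(hd_acc)) stats::setNames(colMeans(hd_acc, na.rm = TRUE),
                                                     names(class_names)),
    hausdorff_mm = if (nrow(hd_acc)) stats::setNames(colMeans(hd_acc, na.rm = TRUE) * spacing,
                                                     names(class_names)),
    mae = mae_n,
    mae_physical = mae_n * phys,
    pcc = pcc_v,
    phase_error_rate = phase_error_rate(pred_tab$phase, true_tab$phase),
    n_frames = nrow(pred_tab), spacing = spacing, image_size = H)
  class(report) <- "lvq_metric_report"
  report
}

#' @export
print.lvq_metric_report <- function(x, ...) {
  cat("LV quantification report (", x$n_frames, " frames, ",
      x$image_size, "px, ", x$spacing, " mm/px)\n", sep = "")
  if (!is.null(x$dice)) {
    cat("  Dice:      ", paste(sprintf("%s %.3f", names(x$dice), x$dice),
                               collapse = "  "), "\n")
    cat("  Hausdorff: ", paste(sprintf("%s %.2fpx", names(x$hausdorff_px),
                                       x$hausdorff_px), collapse = "  "), "\n")
  }
  cat("  MAE (norm):", paste(sprintf("%s %.4f", names(x$mae), x$mae),
                             collapse = "  "), "\n")
  cat("  PCC:       ", paste(sprintf("%s %.3f", names(x$pcc), x$pcc),
                             collapse = "  "), "\n")
  cat("  Phase ER:  ", sprintf("%.3f", x$phase_error_rate), "\n")
  invisible(x)
}

#' Tidy a metric report into one row per metric and target
#' @param x an `lvq_metric_report`
#' @param ... unused
#' @return a tibble with columns `metric`, `target`, `value`
#' @method tidy lvq_metric_report
#' @export
tidy.lvq_metric_report <- function(x, ...) {
  rows <- list()
  if (!is.null(x$dice)) {
    rows <- c(rows, list(
      tibble::tibble(metric = "dice", target = names(x$dice),
                     value = unname(x$dice)),
      tibble::tibble(metric = "hausdorff_px", target = names(x$hausdorff_px),
                     value = unname(x$hausdorff_px))))
  }
  rows <- c(rows, list(
    tibble::tibble(metric = "mae", target = names(x$mae), value = unname(x$mae)),
    tibble::tibble(metric = "mae_physical", target = names(x$mae_physical),
                   value = unname(x$mae_physical)),
    tibble::tibble(metric = "pcc", target = names(x$pcc), value = unname(x$pcc)),
    tibble::tibble(metric = "phase_error_rate", target = "phase",
                   value = x$phase_error_rate)))
  dplyr::bind_rows(rows)
}

#' One-row summary of a metric report
#' @param x an `lvq_metric_report`
#' @param ... unused
#' @return a one-row tibble with headline means
#' @method glance lvq_metric_report
#' @export
glance.lvq_metric_report <- function(x, ...) {
  tibble::tibble(
    mean_dice = if (is.null(x$dice)) NA_real_ else mean(x$dice),
    cavity_dice = if (is.null(x$dice)) NA_real_ else unname(x$dice["cavity"]),
    mean_mae = mean(x$mae),
    mean_pcc = mean(x$pcc),
    phase_error_rate = x$phase_error_rate,
    n_frames = x$n_frames)
}

#' Plot a metric report
#'
#' Bar panels of per-target Dice, normalized MAE and PCC.
#' @param object an `lvq_metric_report`
#' @param ... unused
#' @return a ggplot object
#' @method autoplot lvq_metric_report
#' @export
autoplot.lvq_metric_report <- function(object, ...) {
  td <- tidy(object)
  td <- td[td$metric %in% c("dice", "mae", "pcc"), ]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$target, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Serialise / restore a metric report
#' @param report an `lvq_metric_report`
#' @param path JSON file path
#' @return `write_metric_report`: the path invisibly;
#'   `read_metric_report`: the report
#' @export
write_metric_report <- function(report, path) {
  plain <- unclass(report)
  for (nm in names(plain))           # keep vector names as JSON object keys
    if (!is.null(names(plain[[nm]]))) plain[[nm]] <- as.list(plain[[nm]])
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_metric_report
#' @export
read_metric_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("dice", "hausdorff_px", "hausdorff_mm", "mae", "mae_physical",
               "pcc"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  class(raw) <- "lvq_metric_report"
  raw
}
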