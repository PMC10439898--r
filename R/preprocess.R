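# Preprocessing and training-time augmentation.
#
# A subject's frame stack is contrast-equalised (CLAHE, per frame), then
# z-score normalized over the whole stack; training windows of 5
# consecutive frames (cyclic wrap over the 20-frame cycle) feed both
# network paths, with the centre frame carrying the regression target.

#' Z-score normalize a frame stack
#'
#' Subtracts the mean and divides by the standard deviation computed over
#' the whole stack; a floor on the deviation maps constant stacks to zero.
#' @param images numeric array (any shape)
#' @param floor minimum standard deviation
#' @return array of the same shape with mean ~0, sd ~1
#' @export
zscore <- function(images, floor = 1e-8) {
  (images - mean(images)) / max(stats::sd(images), floor)
}

#' Contrast-limited adaptive histogram equalization of one frame
#'
#' Standard CLAHE on the frame rescaled to `[0, 1]`, with the result mapped
#' back to the input's original range convention.
#'
#' @param image `H x W` numeric matrix
#' @param clip_limit contrast clip limit
#' @param tiles tile grid size (`tiles x tiles`)
#' @return equalized matrix spanning the input's range
#' @export
clahe <- function(image, clip_limit = 2, tiles = 8L) {
  lo <- min(image); hi <- max(image)
  if (hi - lo < 1e-12) return(image)  # no contrast to equalize
  x <- (image - lo) / (hi - lo)
  eq <- EBImage::clahe(EBImage::Image(x), nx = tiles, ny = tiles,
                       limit = clip_limit)
  eq <- as.matrix(EBImage::imageData(eq))
  eq <- (eq - min(eq)) / max(max(eq) - min(eq), 1e-12)
  lo + eq * (hi - lo)
}

#' Build the 5-frame temporal window centred on one frame
#'
#' Frames `t-2 ... t+2` with cyclic wrap-around over the cardiac cycle; the
#' regression target is the index row of the centre frame.
#'
#' @param subject an `lvq_subject` (images, masks, indices)
#' @param t 0-based centre frame index
#' @param width window width (odd)
#' @return an `lvq_window`: list with `frames` (`H x W x width`), `masks`
#'   (same shape, or `NULL`), `target` (one index row), `center_frame`
#' @export
temporal_window <- function(subject, t, width = 5L) {
  n <- dim(subject$images)[3]
  if (n < width) stop("subject must have at least ", width, " frames")
  if (t < 0 || t >= n) stop("frame index out of range")
  idx <- ((t + seq_len(width) - 1L - (width - 1L) %/% 2L) %% n) + 1L
  structure(list(
    frames = subject$images[, , idx, drop = FALSE],
    masks = if (!is.null(subject$masks)) subject$masks[, , idx, drop = FALSE],
    target = subject$indices[subject$indices$frame == t, ],
    center_frame = t), class = "lvq_window")
}

# Bilinear (images) / nearest-neighbour (masks) sampling of a frame at
# continuous 0-based source coordinates; outside pixels take `fill`.
sample_frame <- function(frame, src_r, src_c, nearest = FALSE, fill = 0) {
  H <- nrow(frame); W <- ncol(frame)
  if (nearest) {
    r <- round(src_r); c <- round(src_c)
    ok <- r >= 0 & r < H & c >= 0 & c < W
    out <- rep(fill, length(src_r))
    out[ok] <- frame[cbind(r[ok] + 1L, c[ok] + 1L)]
    return(matrix(out, H, W))
  }
  r0 <- floor(src_r); c0 <- floor(src_c)
  fr <- src_r - r0; fc <- src_c - c0
  val <- function(rr, cc) {
    ok <- rr >= 0 & rr < H & cc >= 0 & cc < W
    v <- rep(fill, length(rr))
    v[ok] <- frame[cbind(rr[ok] + 1L, cc[ok] + 1L)]
    v
  }
  out <- val(r0, c0) * (1 - fr) * (1 - fc) + val(r0 + 1, c0) * fr * (1 - fc) +
    val(r0, c0 + 1) * (1 - fr) * fc + val(r0 + 1, c0 + 1) * fr * fc
  matrix(out, H, W)
}

# Smooth random displacement field: offsets drawn on a coarse control grid
# and interpolated bilinearly to pixel resolution.
elastic_field <- function(H, W, spacing = 16, sigma = 2) {
  gh <- max(2L, ceiling(H / spacing) + 1L)
  gw <- max(2L, ceiling(W / spacing) + 1L)
  up <- function(g) {
    rows <- seq(0, gh - 1, length.out = H)
    cols <- seq(0, gw - 1, length.out = W)
    r0 <- pmin(floor(rows), gh - 2); c0 <- pmin(floor(cols), gw - 2)
    fr <- rows - r0; fc <- cols - c0
    m <- outer(seq_len(H), seq_len(W), function(i, j) {
      ri <- r0[i] + 1L; ci <- c0[j] + 1L
      g[cbind(ri, ci)] * (1 - fr[i]) * (1 - fc[j]) +
        g[cbind(ri + 1L, ci)] * fr[i] * (1 - fc[j]) +
        g[cbind(ri, ci + 1L)] * (1 - fr[i]) * fc[j] +
        g[cbind(ri + 1L, ci + 1L)] * fr[i] * fc[j]
    })
    m
  }
  list(dr = up(matrix(stats::rnorm(gh * gw, 0, sigma), gh, gw)),
       dc = up(matrix(stats::rnorm(gh * gw, 0, sigma), gh, gw)))
}

#' Randomly augment a training window
#'
#' One spatial transform — rotation in (-90, 90) degrees, horizontal and
#' vertical flips each with probability 1/2, and a smooth elastic
#' deformation — is drawn and applied identically to all frames (bilinear)
#' and all masks (nearest-neighbour); a gamma shift in `[0.5, 1.5]` is then
#' applied to the images only. Draws come from the current RNG state.
#'
#' @param window an `lvq_window` with masks present
#' @param rotation_range degrees; rotation drawn uniformly in `+/-` this
#' @param gamma_range range of the gamma exponent
#' @param elastic_spacing,elastic_sigma control-point spacing and offset
#'   standard deviation (pixels) of the elastic field; `elastic_sigma = 0`
#'   disables it
#' @param p_flip probability of each flip
#' @return the transformed `lvq_window`
#' @export
augment <- function(window, rotation_range = 90, gamma_range = c(0.5, 1.5),
                    elastic_spacing = 16, elastic_sigma = 2, p_flip = 0.5) {
  if (is.null(window$masks)) stop("augment requires a training window with masks")
  d <- dim(window$frames)
  H <- d[1]; W <- d[2]
  ang <- stats::runif(1, -rotation_range, rotation_range) * pi / 180
  hflip <- stats::runif(1) < p_flip
  vflip <- stats::runif(1) < p_flip
  gamma <- stats::runif(1, gamma_range[1], gamma_range[2])
  ef <- if (elastic_sigma > 0) elastic_field(H, W, elastic_spacing, elastic_sigma)
        else list(dr = 0, dc = 0)

  # destination pixel grid (0-based), mapped backwards through the
  # composite transform: un-flip, un-rotate about the image centre, then
  # displace by the elastic field
  idx <- seq_len(H) - 1L
  dst_r <- matrix(idx, H, W)
  dst_c <- matrix(idx, H, W, byrow = TRUE)
  r <- dst_r; c <- dst_c
  if (hflip) c <- (W - 1) - c
  if (vflip) r <- (H - 1) - r
  cr <- (H - 1) / 2; cc <- (W - 1) / 2
  dr <- r - cr; dc <- c - cc
  src_r <- cr + cos(ang) * dr - sin(ang) * dc + ef$dr
  src_c <- cc + sin(ang) * dr + cos(ang) * dc + ef$dc

  frames <- window$frames
  masks <- window$masks
  for (k in seq_len(d[3])) {
    fr <- sample_frame(window$frames[, , k], src_r, src_c, fill = min(window$frames))
    lo <- min(fr); hi <- max(fr)
    if (hi - lo > 1e-12) {
      fr <- lo + ((fr - lo) / (hi - lo))^gamma * (hi - lo)
    }
    frames[, , k] <- fr
    masks[, , k] <- sample_frame(window$masks[, , k], src_r, src_c,
                                 nearest = TRUE, fill = 0)
  }
  storage.mode(masks) <- "integer"
  window$frames <- frames
  window$masks <- masks
  window
}

#' Preprocess a subject for the networks
#'
#' CLAHE per frame (optional) followed by z-score normalization over the
#' stack; applied identically at training and evaluation time so the input
#' distribution matches.
#'
#' @param subject an `lvq_subject`
#' @param use_clahe apply CLAHE before normalization
#' @param clip_limit,tiles CLAHE parameters
#' @return the subject with normalized `images`
#' @export
preprocess_subject <- function(subject, use_clahe = TRUE, clip_limit = 2,
                               tiles = 8L) {
  imgs <- subject$images
  if (use_clahe) {
    for (f in seq_len(dim(imgs)[3]))
      imgs[, , f] <- clahe(imgs[, , f], clip_limit, tiles)
  }
  subject$images <- zscore(imgs)
  subject
}
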