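# Parametric beating-LV phantom.
#
# The phantom is a continuous model of a short-axis mid-cavity slice: an
# endocardial boundary (a perturbed circle) contracting from end-diastole
# (ED) to end-systole (ES) along a raised-cosine temporal profile, wrapped
# by a myocardial ring whose per-segment thickness increases in systole.
# Images, hard 3-class masks and analytically exact index values all derive
# from the same continuous specification, which makes the generator an
# oracle for the mask-based geometry and for the learned regressor.

#' Create a phantom specification
#'
#' @param image_size frame side length in pixels (square frames)
#' @param n_frames number of frames in one cardiac cycle
#' @param center subpixel LV center, 0-based `(row, col)`
#' @param r_endo_ed,r_endo_es endocardial radius (pixels) at ED / ES
#' @param wall_ed,wall_es per-segment wall thickness (pixels) at ED / ES,
#'   length 6 in the order IS, I, IL, AL, A, AS
#' @param fourier_amp,fourier_phase amplitudes (dimensionless, each
#'   `<= 0.1`) and phases of low-order angular perturbations of the
#'   endocardial radius, harmonic orders `2, 3, ...`
#' @param es_frame 0-based frame index of end-systole
#' @param intensity mean grey level of `(background, myocardium, cavity)`
#'   on a 0-1 scale
#' @param noise_sigma additive Gaussian noise standard deviation
#' @param bias_amp amplitude of the multiplicative low-frequency bias field
#' @param seed integer seed used when rendering noise and bias phases
#' @return an object of class `lvq_phantom_spec`
#' @export
phantom_spec <- function(image_size = 80L, n_frames = 20L,
                         center = NULL,
                         r_endo_ed = 20, r_endo_es = 14,
                         wall_ed = rep(8, 6), wall_es = rep(11, 6),
                         fourier_amp = numeric(0),
                         fourier_phase = numeric(0),
                         es_frame = 9L,
                         intensity = c(background = 0.2, myocardium = 0.45,
                                       cavity = 0.8),
                         noise_sigma = 0, bias_amp = 0, seed = 0L) {
  if (is.null(center)) center <- rep((image_size - 1) / 2, 2)
  spec <- structure(
    list(image_size = as.integer(image_size), n_frames = as.integer(n_frames),
         center = as.numeric(center),
         r_endo_ed = r_endo_ed, r_endo_es = r_endo_es,
         wall_ed = as.numeric(wall_ed), wall_es = as.numeric(wall_es),
         fourier_amp = as.numeric(fourier_amp),
         fourier_phase = as.numeric(fourier_phase),
         es_frame = as.integer(es_frame),
         intensity = intensity, noise_sigma = noise_sigma,
         bias_amp = bias_amp, seed = as.integer(seed)),
    class = "lvq_phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(length(spec$wall_ed) == 6L, length(spec$wall_es) == 6L,
            length(spec$fourier_amp) == length(spec$fourier_phase))
  if (spec$r_endo_es >= spec$r_endo_ed)
    stop("r_endo_es must be smaller than r_endo_ed (systolic contraction)")
  if (any(spec$wall_es < spec$wall_ed))
    stop("wall must not thin in systole (wall_es >= wall_ed)")
  if (spec$es_frame <= 0L || spec$es_frame >= spec$n_frames)
    stop("es_frame must lie strictly inside the cycle")
  if (any(abs(spec$fourier_amp) > 0.1))
    stop("fourier perturbation amplitudes must stay below 0.1")
  pert <- 1 + sum(abs(spec$fourier_amp))
  reach <- spec$r_endo_ed * pert + max(c(spec$wall_ed, spec$wall_es))
  margin <- max(abs(spec$center - (spec$image_size - 1) / 2))
  if (reach + margin >= spec$image_size / 2)
    stop("phantom does not fit inside the frame")
  invisible(spec)
}

#' Draw a random phantom specification
#'
#' `easy` yields a concentric, noiseless phantom (circular boundaries,
#' uniform wall); `realistic` draws per-segment wall asymmetry, angular
#' shape perturbations, intensity bias and noise. Uses the current RNG
#' state, so results are reproducible under [set.seed()].
#'
#' @param difficulty `"easy"` or `"realistic"`
#' @param image_size frame side length in pixels; parameter ranges scale
#'   with it so the anatomy keeps its proportions
#' @return an [phantom_spec()] object
#' @export
sample_phantom_spec <- function(difficulty = c("realistic", "easy"),
                                image_size = 80L) {
  difficulty <- match.arg(difficulty)
  s <- image_size / 80
  seed <- sample.int(.Machine$integer.max, 1L)
  if (difficulty == "easy") {
    r_ed <- stats::runif(1, 16, 21) * s
    wall <- stats::runif(1, 6, 10) * s
    return(phantom_spec(image_size = image_size,
                        center = rep((image_size - 1) / 2, 2),
                        r_endo_ed = r_ed,
                        r_endo_es = r_ed * stats::runif(1, 0.62, 0.75),
                        wall_ed = rep(wall, 6),
                        wall_es = rep(wall * stats::runif(1, 1.3, 1.45), 6),
                        es_frame = 9L, noise_sigma = 0, bias_amp = 0,
                        seed = seed))
  }
  repeat {
    # Cohort-style variability: endocardial radii span dysfunction-to-normal
    # contraction; ED wall 4-12 px (6-19 mm at the modal spacing) spans
    # normal to hypertrophic myocardium; systolic thickening 15-55%. The
    # upper wall bound is capped so the subject fits the frame.
    r_ed <- stats::runif(1, 12, 20) * s
    r_es <- r_ed * stats::runif(1, 0.5, 0.8)
    wall_cap <- (image_size / 2 - 3.5 * s - r_ed * 1.12) / 1.55
    wall_ed <- stats::runif(6, 4 * s, max(5 * s, min(12 * s, wall_cap)))
    wall_es <- wall_ed * stats::runif(6, 1.15, 1.55)
    amp <- stats::runif(3, 0, 0.05) * c(1, 0.6, 0.4)
    ph <- stats::runif(3, 0, 2 * pi)
    ctr <- (image_size - 1) / 2 + stats::runif(2, -3, 3) * s
    spec <- try(phantom_spec(
      image_size = image_size, center = ctr,
      r_endo_ed = r_ed, r_endo_es = r_es,
      wall_ed = wall_ed, wall_es = wall_es,
      fourier_amp = amp, fourier_phase = ph,
      es_frame = sample(8:12, 1L),
      noise_sigma = stats::runif(1, 0.02, 0.05),
      bias_amp = stats::runif(1, 0.05, 0.15),
      seed = sample.int(.Machine$integer.max, 1L)), silent = TRUE)
    if (!inherits(spec, "try-error")) return(spec)
  }
}

# Raised-cosine contraction profile: 0 at frame 0 (ED), 1 at es_frame (ES),
# periodic over the cycle with zero slope at both extremes.
contraction_profile <- function(spec, frame) {
  n <- spec$n_frames; es <- spec$es_frame
  g <- ifelse(frame <= es, 0.5 * frame / es, 0.5 + 0.5 * (frame - es) / (n - es))
  0.5 * (1 - cos(2 * pi * g))
}

# Angular shape modulation shared by both surfaces.
shape_factor <- function(spec, angle) {
  f <- rep(1, length(angle))
  for (k in seq_along(spec$fourier_amp))
    f <- f + spec$fourier_amp[k] * cos((k + 1) * angle + spec$fourier_phase[k])
  f
}

# Piecewise-linear periodic interpolation of the six per-segment wall
# thickness values across angle; equals the segment value exactly at its
# bisector.
wall_at_angle <- function(spec, frame, angle) {
  c_t <- contraction_profile(spec, frame)
  w6 <- spec$wall_ed + (spec$wall_es - spec$wall_ed) * c_t
  ord <- order(lvq_segment_angles)
  ang6 <- lvq_segment_angles[ord]     # ascending within [0, 2pi)
  val6 <- w6[ord]
  a <- (angle - ang6[1]) %% (2 * pi)  # position relative to first bisector
  seg <- pmin(floor(a / (pi / 3)) + 1, 6)
  frac <- a / (pi / 3) - (seg - 1)
  nxt <- seg %% 6 + 1
  val6[seg] * (1 - frac) + val6[nxt] * frac
}

#' Continuous boundary radius of the phantom
#'
#' @param spec a [phantom_spec()]
#' @param frame 0-based frame index
#' @param angle polar angle(s), radians
#' @param surface `"endo"` or `"epi"`
#' @return radius in pixels (vectorized over `angle`)
#' @export
boundary_radius <- function(spec, frame, angle, surface = c("endo", "epi")) {
  surface <- match.arg(surface)
  if (frame < 0 || frame >= spec$n_frames)
    stop("frame out of range [0, ", spec$n_frames - 1, "]")
  c_t <- contraction_profile(spec, frame)
  base <- spec$r_endo_ed + (spec$r_endo_es - spec$r_endo_ed) * c_t
  r <- base * shape_factor(spec, angle)
  if (surface == "epi") r <- r + wall_at_angle(spec, frame, angle)
  r
}

# Fine composite-trapezoid quadrature of f(theta) over [0, 2pi), aligned to
# the six segment boundaries so the piecewise-linear wall is integrated
# exactly on smooth sub-intervals.
quad_angle <- function(f, n_per_sector = 2048L) {
  edges <- sort(lvq_segment_angles) - pi / 6  # sector boundaries
  edges <- c(edges, edges[1] + 2 * pi)
  total <- 0
  for (k in 1:6) {
    th <- seq(edges[k], edges[k + 1], length.out = n_per_sector + 1L)
    y <- f(th)
    h <- (edges[k + 1] - edges[k]) / n_per_sector
    total <- total + h * (sum(y) - (y[1] + y[length(y)]) / 2)
  }
  total
}

#' Analytically exact indices of a phantom frame
#'
#' Areas are computed as polar integrals of the continuous boundaries
#' (normalized by the pixel count), dimensions as paired endocardial radii
#' along the three dimension axes (normalized by the image height), and
#' regional wall thicknesses as the continuous wall at the six segment
#' bisectors. The phase column requires the whole cycle and is filled by
#' [analytic_index_table()].
#'
#' @param spec a [phantom_spec()]
#' @param frame 0-based frame index
#' @return a one-row tibble with the eleven index columns
#' @export
analytic_indices <- function(spec, frame) {
  if (frame < 0 || frame >= spec$n_frames)
    stop("frame out of range [0, ", spec$n_frames - 1, "]")
  H <- spec$image_size
  endo <- function(th) boundary_radius(spec, frame, th, "endo")
  epi <- function(th) boundary_radius(spec, frame, th, "epi")
  a_cav <- unname(0.5 * quad_angle(function(th) endo(th)^2) / (H * H))
  a_myo <- unname(0.5 * quad_angle(function(th) epi(th)^2 - endo(th)^2) /
                    (H * H))
  dims <- unname(vapply(lvq_dim_angles, function(th)
    (endo(th) + endo(th + pi)) / H, numeric(1)))
  rwt <- unname(vapply(lvq_segment_angles, function(th)
    (epi(th) - endo(th)) / H, numeric(1)))
  out <- tibble::tibble(area_cav = a_cav, area_myo = a_myo,
                        dim1 = dims[1], dim2 = dims[2], dim3 = dims[3])
  out[paste0("rwt_", names(lvq_segment_angles))] <- as.list(rwt)
  out
}

#' Full analytic index table of a phantom (all frames plus phase)
#'
#' @param spec a [phantom_spec()]
#' @return a tibble with one row per frame: `frame`, the eleven indices and
#'   the binary `phase` (1 = systole)
#' @export
analytic_index_table <- function(spec) {
  rows <- lapply(seq_len(spec$n_frames) - 1L, function(f)
    analytic_indices(spec, f))
  tab <- dplyr::bind_rows(rows)
  tab <- dplyr::mutate(tab, frame = seq_len(spec$n_frames) - 1L,
                       .before = 1L)
  tab$phase <- phase_from_areas(tab$area_cav)
  tab
}

#' Render a phantom subject (images, masks, truth table)
#'
#' Each frame is rasterized by classifying every pixel center's distance to
#' the LV center against the continuous endo/epi radii at the pixel's polar
#' angle (hard 3-class field, no antialiasing). The image assigns the class
#' mean grey levels, multiplies a low-frequency bias field, adds Gaussian
#' noise and clips to `[0, 1]`. Deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec()]
#' @param id subject identifier
#' @return an `lvq_subject`: list with `id`, `images` and `masks` (arrays of
#'   dim `H x W x n_frames`; mask codes 0 background, 1 cavity,
#'   2 myocardium), `indices` (analytic truth tibble), `spacing`, `spec`
#' @export
render_subject <- function(spec, id = "phantom") {
  H <- spec$image_size
  n <- spec$n_frames
  idx <- seq_len(H) - 1L
  rowg <- matrix(idx, H, H)               # row coordinate of each pixel
  colg <- matrix(idx, H, H, byrow = TRUE)
  dr <- spec$center[1] - rowg
  dc <- colg - spec$center[2]
  rad <- sqrt(dr * dr + dc * dc)
  th <- atan2(dr, dc)
  images <- array(0, dim = c(H, H, n))
  masks <- array(0L, dim = c(H, H, n))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(spec$seed)
  bias_phase <- stats::runif(2, 0, 2 * pi)
  bias <- 1 + spec$bias_amp *
    cos(2 * pi * rowg / H + bias_phase[1]) *
    cos(2 * pi * colg / H + bias_phase[2])
  for (f in seq_len(n) - 1L) {
    r_endo <- boundary_radius(spec, f, th, "endo")
    r_epi <- boundary_radius(spec, f, th, "epi")
    m <- matrix(0L, H, H)
    m[rad < r_epi] <- 2L
    m[rad < r_endo] <- 1L
    img <- matrix(spec$intensity[m + 1L], H, H)
    img <- img * bias
    if (spec$noise_sigma > 0)
      img <- img + matrix(stats::rnorm(H * H, 0, spec$noise_sigma), H, H)
    images[, , f + 1L] <- pmin(pmax(img, 0), 1)
    masks[, , f + 1L] <- m
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  structure(list(id = id, images = images, masks = masks,
                 indices = analytic_index_table(spec),
                 spacing = lvq_default_spacing, spec = spec),
            class = "lvq_subject")
}

#' Generate a phantom cohort, optionally writing it to disk
#'
#' @param n_subjects number of subjects
#' @param difficulty passed to [sample_phantom_spec()]
#' @param dir output directory (one sub-directory per subject with NIfTI
#'   volumes and `indices.csv`); `NULL` keeps the cohort in memory only
#' @param image_size frame side length in pixels
#' @return invisibly, a list of `lvq_subject` objects
#' @export
generate_dataset <- function(n_subjects, difficulty = "realistic",
                             dir = NULL, image_size = 80L) {
  stopifnot(n_subjects >= 1)
  subjects <- lapply(seq_len(n_subjects), function(i) {
    spec <- sample_phantom_spec(difficulty, image_size = image_size)
    render_subject(spec, id = sprintf("subject_%03d", i))
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
      stop("cannot create dataset directory: ", dir)
    for (s in subjects) write_subject(s, file.path(dir, s$id))
  }
  invisible(subjects)
}
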