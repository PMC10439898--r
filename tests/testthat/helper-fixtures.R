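# Shared fixtures, built once per test run.

# Noiseless concentric phantom subject (80 px, r_endo 20, wall 8 -> 11).
easy_subject <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- render_subject(phantom_spec(), id = "easy")
    cache
  }
})

# A small cohort of realistic phantoms at 80 px.
realistic_subjects <- local({
  cache <- NULL
  function(n = 5) {
    if (is.null(cache) || length(cache) < n) {
      set.seed(404)
      cache <<- lapply(seq_len(n), function(i)
        render_subject(sample_phantom_spec("realistic"), id = sprintf("r%02d", i)))
    }
    cache[seq_len(n)]
  }
})

# Concentric annulus mask: cavity radius r_in, outer radius r_out.
annulus_mask <- function(H = 80, r_in = 20, r_out = 28,
                         center = c((H - 1) / 2, (H - 1) / 2)) {
  idx <- seq_len(H) - 1
  rr <- matrix(idx, H, H)
  cc <- matrix(idx, H, H, byrow = TRUE)
  d <- sqrt((rr - center[1])^2 + (cc - center[2])^2)
  m <- matrix(0L, H, H)
  m[d < r_out] <- 2L
  m[d < r_in] <- 1L
  m
}

# Elliptical cavity in a generous ring.
ellipse_mask <- function(H = 80, a = 25, b = 15, ring = 6) {
  idx <- seq_len(H) - 1
  rr <- matrix(idx, H, H)
  cc <- matrix(idx, H, H, byrow = TRUE)
  c0 <- (H - 1) / 2
  # axes: a along columns (angle 0), b along rows
  q <- ((cc - c0) / a)^2 + ((rr - c0) / b)^2
  qo <- ((cc - c0) / (a + ring))^2 + ((rr - c0) / (b + ring))^2
  m <- matrix(0L, H, H)
  m[qo < 1] <- 2L
  m[q < 1] <- 1L
  m
}

# Rotate a square mask by +90 degrees in the package's angular convention
# (new(row', col') = old taken at the -90-degree position).
rot90_mask <- function(m) {
  H <- nrow(m)
  out <- m
  for (i in seq_len(H)) for (j in seq_len(H)) out[H + 1 - j, i] <- m[i, j]
  out
}

rwt_cols <- paste0("rwt_", c("is", "i", "il", "al", "a", "as"))
dim_cols <- c("dim1", "dim2", "dim3")

# Small network configurations used across network/trainer tests.
test_seg_config <- function(image_hw = 48L) {
  seg_config(stem_channels = c(2L, 4L, 8L), hidden = 16L, depth = 1L,
             heads = 2L, decoder_channels = c(8L, 8L, 4L, 4L),
             image_hw = image_hw)
}

test_reg_config <- function() {
  reg_config(channels = c(2L, 4L, 8L), recurrence = 1L, phase_hidden = 12L)
}
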