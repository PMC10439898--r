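# Centroid ray-casting morphometry.

test_that("cavity centroid is the mean of cavity pixel centres", {
  m <- matrix(0L, 40, 40)
  m[11, 21] <- 1L  # 0-based (10, 20)
  expect_equal(unname(cavity_centroid(m)), c(10, 20))

  expect_equal(unname(cavity_centroid(annulus_mask())), c(39.5, 39.5),
               tolerance = 1e-9)

  # L-shaped cavity: brute-force pixel enumeration oracle
  m <- matrix(0L, 20, 20)
  px <- rbind(cbind(5:9, 5), cbind(9, 6:8))
  m[px] <- 1L
  expect_equal(unname(cavity_centroid(m)), colMeans(px) - 1)

  expect_error(cavity_centroid(matrix(0L, 5, 5)), "empty cavity")
})

test_that("areas are normalized pixel counts", {
  m <- matrix(0L, 80, 80)
  m[1:10, 1:10] <- 1L
  m[30:34, 30:39] <- 2L
  expect_equal(unname(areas_from_mask(m)), c(100 / 6400, 50 / 6400))
  expect_equal(unname(areas_from_mask(matrix(0L, 80, 80))), c(0, 0))
  # rasterized concentric phantom vs continuous areas within 2%
  a <- areas_from_mask(easy_subject()$masks[, , 1])
  expect_equal(unname(a[1]), pi * 400 / 6400, tolerance = 0.02)
  expect_equal(unname(a[2]), pi * (28^2 - 400) / 6400, tolerance = 0.02)
})

test_that("ray crossings localise the phantom boundaries", {
  m <- easy_subject()$masks[, , 1]
  ctr <- c(39.5, 39.5)
  for (ang in c(0, pi / 3, 2.1)) {
    tr <- ray_crossings(m, ctr, ang)
    expect_identical(tr$from[1:2], c(1L, 2L))
    expect_identical(tr$to[1:2], c(2L, 0L))
    expect_equal(tr$distance[1], 20, tolerance = 0.75)
    expect_equal(tr$distance[2], 28, tolerance = 0.75)
    # step refinement moves crossings by less than 0.1 px
    tr2 <- ray_crossings(m, ctr, ang, step = 0.05)
    expect_lt(max(abs(tr$distance[1:2] - tr2$distance[1:2])), 0.1)
  }
  expect_identical(nrow(ray_crossings(matrix(0L, 40, 40), c(20, 20), 1)), 0L)
  expect_error(ray_crossings(m, c(-5, 0), 0), "outside")
})

test_that("cavity dimensions match circle and ellipse oracles", {
  d <- cavity_dimensions(annulus_mask())
  expect_equal(unname(d), rep(0.5, 3), tolerance = 1.5 / 80 / 0.5)

  # axis-aligned ellipse: polar radius oracle along each dimension axis
  m <- ellipse_mask(a = 25, b = 15)
  d <- cavity_dimensions(m)
  polar_r <- function(th) {
    ct <- cos(th); st <- sin(th)
    1 / sqrt((ct / 25)^2 + (st / 15)^2)
  }
  expected <- vapply(lvquant::lvq_segment_angles[c("is", "i", "il")],
                     function(th) 2 * polar_r(th) / 80, numeric(1))
  expected2 <- vapply(c(210, 270, 330) * pi / 180,
                      function(th) 2 * polar_r(th) / 80, numeric(1))
  expect_equal(unname(d), unname(expected2), tolerance = 1.5 / 80 / 0.3)

  cav_only <- matrix(0L, 40, 40); cav_only[15:25, 15:25] <- 1L
  expect_error(cavity_dimensions(cav_only), "degenerate")
})

test_that("regional wall thickness matches annulus and scaled-wall oracles", {
  r <- regional_wall_thickness(annulus_mask(r_in = 20, r_out = 30))
  expect_equal(unname(r), rep(10 / 80, 6), tolerance = 1.5 / 80 / 0.125)

  # doubling one segment's wall doubles its rwt
  sp <- phantom_spec(wall_ed = c(6, 6, 6, 6, 12, 6),
                     wall_es = c(8, 8, 8, 8, 14, 8))
  m <- render_subject(sp)$masks[, , 1]
  r <- regional_wall_thickness(m)
  expect_equal(unname(r["rwt_a"] / r["rwt_is"]), 2, tolerance = 0.12)

  cav_only <- matrix(0L, 40, 40); cav_only[15:25, 15:25] <- 1L
  expect_error(regional_wall_thickness(cav_only), "empty myocardium")
})

test_that("broken rings raise errors instead of returning zeros", {
  m <- annulus_mask()
  m[, 41:80][m[, 41:80] == 2L] <- 0L  # remove right half of the ring
  expect_error(regional_wall_thickness(m), "broken|epicardial")
})

test_that("phase labelling follows the ED -> ES systole rule", {
  v <- c(10:1, 2:11)  # max at frame 19, min at frame 9
  ph <- phase_from_areas(v)
  expect_identical(ph, c(rep(1L, 10), rep(0L, 10)))  # cyclic: 19 -> 9
  # reversed series: ED moves to frame 0, ES to frame 10
  pr <- phase_from_areas(rev(v))
  expect_identical(which(pr == 1L) - 1L, 1:10)
  expect_error(phase_from_areas(rep(1, 10)), "constant")
  expect_error(phase_from_areas(c(1, 2)), "3 frames")
  # cyclic wrap when ES precedes ED
  ph2 <- phase_from_areas(c(1, 2, 3, 2))  # ED at 2, ES at 0
  expect_identical(ph2, c(1L, 0L, 0L, 1L))
})

test_that("indices_from_mask closes the loop on phantom subjects", {
  sub <- easy_subject()
  est <- indices_from_mask(sub$masks)
  tr <- sub$indices
  expect_lt(max(abs(est$area_cav - tr$area_cav)), 0.003)
  expect_lt(max(abs(as.matrix(est[rwt_cols]) - as.matrix(tr[rwt_cols]))),
            1.5 / 80)
  expect_lt(max(abs(as.matrix(est[dim_cols]) - as.matrix(tr[dim_cols]))),
            1.5 / 80)
  expect_identical(est$phase, tr$phase)

  # identical masks for all frames: constant areas -> undefined phase
  const <- array(sub$masks[, , 1], dim = c(80, 80, 4))
  expect_error(indices_from_mask(const), "constant")

  # degeneracy reports the frame index
  broken <- sub$masks[, , 1:3]
  broken[, , 2][broken[, , 2] == 1L] <- 0L
  expect_error(indices_from_mask(broken), "frame 1")
})

test_that("90-degree rotation preserves areas; 180 degrees permutes segments", {
  set.seed(88)
  sub <- realistic_subjects(1)[[1]]
  m <- sub$masks[, , 5]
  a0 <- areas_from_mask(m)
  m90 <- rot90_mask(m)
  expect_equal(areas_from_mask(m90), a0)

  m180 <- rot90_mask(m90)
  r0 <- regional_wall_thickness(m)
  r180 <- regional_wall_thickness(m180)
  # opposite segments swap: IS<->AL, I<->A, IL<->AS
  perm <- c(rwt_is = "rwt_al", rwt_i = "rwt_a", rwt_il = "rwt_as",
            rwt_al = "rwt_is", rwt_a = "rwt_i", rwt_as = "rwt_il")
  expect_equal(unname(r180[names(perm)]), unname(r0[perm]),
               tolerance = 1.5 / 80 / 0.05)
  d0 <- cavity_dimensions(m)
  d180 <- cavity_dimensions(m180)
  expect_equal(unname(d180), unname(d0), tolerance = 1.5 / 80 / 0.3)
})

test_that("2x nearest-neighbour upsampling leaves normalized indices stable", {
  m <- easy_subject()$masks[, , 8]
  up <- m[rep(1:80, each = 2), rep(1:80, each = 2)]
  i1 <- c(areas_from_mask(m), cavity_dimensions(m), regional_wall_thickness(m))
  i2 <- c(areas_from_mask(up), cavity_dimensions(up), regional_wall_thickness(up))
  expect_lt(max(abs(i1 - i2)), 1 / 80)
})
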