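# Phantom simulator: spec sampling, boundary model, rasterization and
# analytic ground truth.

test_that("easy specs are concentric, noiseless and deterministic", {
  set.seed(0)
  sp <- sample_phantom_spec("easy")
  expect_length(sp$fourier_amp, 0)
  expect_identical(sp$noise_sigma, 0)
  expect_identical(sp$bias_amp, 0)
  set.seed(7); a <- sample_phantom_spec("realistic")
  set.seed(7); b <- sample_phantom_spec("realistic")
  expect_identical(a, b)
})

test_that("sampled realistic specs always fit inside the frame", {
  set.seed(123)
  for (i in 1:1000) {
    sp <- sample_phantom_spec("realistic")
    pert <- 1 + sum(abs(sp$fourier_amp))
    reach <- sp$r_endo_ed * pert + max(c(sp$wall_ed, sp$wall_es))
    margin <- max(abs(sp$center - (sp$image_size - 1) / 2))
    expect_lt(reach + margin, sp$image_size / 2)
    expect_lt(sp$r_endo_es, sp$r_endo_ed)
    expect_true(all(sp$wall_es >= sp$wall_ed))
  }
})

test_that("spec invariants are enforced", {
  expect_error(phantom_spec(r_endo_es = 25), "contraction")
  expect_error(phantom_spec(wall_es = rep(5, 6)), "thin")
  expect_error(phantom_spec(es_frame = 0L), "strictly inside")
  expect_error(phantom_spec(r_endo_ed = 30, wall_ed = rep(12, 6),
                            wall_es = rep(14, 6)), "fit")
})

test_that("boundary radius hits the ED and ES values and stays periodic", {
  sp <- phantom_spec()
  th <- seq(0, 2 * pi, length.out = 17)
  expect_equal(boundary_radius(sp, 0, th, "endo"), rep(sp$r_endo_ed, 17))
  expect_equal(boundary_radius(sp, sp$es_frame, th, "endo"),
               rep(sp$r_endo_es, 17))
  expect_equal(boundary_radius(sp, 3, th, "epi"),
               boundary_radius(sp, 3, th + 2 * pi, "epi"))
  expect_error(boundary_radius(sp, 20, 0), "range")

  # realistic spec: epi radius stays inside the half-frame at all angles
  set.seed(21)
  spr <- sample_phantom_spec("realistic")
  th <- seq(0, 2 * pi, length.out = 720)
  for (f in 0:(spr$n_frames - 1))
    expect_lt(max(boundary_radius(spr, f, th, "epi")),
              spr$image_size / 2 - max(abs(spr$center - (spr$image_size - 1) / 2)))
})

test_that("rendering rasterizes the continuous model faithfully", {
  sub <- easy_subject()
  sp <- sub$spec
  m0 <- sub$masks[, , 1]
  ctr <- sp$center + 1  # 1-based index of the centre pixel region
  expect_identical(m0[round(ctr[1]), round(ctr[2])], 1L)
  # noiseless image has exactly 3 grey values
  expect_length(unique(as.numeric(sub$images)), 3L)
  # cavity pixel count vs continuous area within 2%
  expect_lt(abs(sum(m0 == 1L) - pi * 20^2) / (pi * 20^2), 0.02)
  # cavity enclosed by the ring: cavity pixels never touch background
  inner <- m0[2:79, 2:79]
  nb <- pmin(m0[1:78, 2:79], m0[3:80, 2:79], m0[2:79, 1:78], m0[2:79, 3:80])
  expect_false(any(inner == 1L & nb == 0L))
  # deterministic rendering
  set.seed(5)
  spr <- sample_phantom_spec("realistic")
  expect_identical(render_subject(spr)$images, render_subject(spr)$images)
})

test_that("analytic indices match closed forms for the concentric phantom", {
  sp <- phantom_spec()  # r_endo 20, wall 8, H 80 at frame 0
  tr <- analytic_indices(sp, 0)
  expect_equal(tr$area_cav, pi * 400 / 6400, tolerance = 1e-6)
  expect_equal(tr$area_myo, pi * (28^2 - 400) / 6400, tolerance = 1e-6)
  for (j in dim_cols) expect_equal(tr[[j]], 0.5, tolerance = 1e-9)
  for (j in rwt_cols) expect_equal(tr[[j]], 0.1, tolerance = 1e-9)
})

test_that("walls thicken towards end-systole in the analytic truth", {
  set.seed(31)
  sp <- sample_phantom_spec("realistic")
  t0 <- analytic_indices(sp, 0)
  tes <- analytic_indices(sp, sp$es_frame)
  for (j in rwt_cols) expect_gt(tes[[j]], t0[[j]])
})

test_that("area quadrature agrees with a brute-force Riemann sum", {
  set.seed(55)
  sp <- sample_phantom_spec("realistic")
  tr <- analytic_indices(sp, 4)
  th <- seq(0, 2 * pi, length.out = 1e6 + 1)[-1]
  r <- boundary_radius(sp, 4, th, "endo")
  riemann <- 0.5 * sum(r^2) * (2 * pi / 1e6) / 6400
  expect_equal(tr$area_cav, riemann, tolerance = 1e-6)
})

test_that("the cavity-area series has a single minimum at es_frame", {
  set.seed(77)
  sp <- sample_phantom_spec("realistic")
  areas <- analytic_index_table(sp)$area_cav
  expect_equal(which.min(areas) - 1L, sp$es_frame)
  expect_equal(which.max(areas) - 1L, 0L)
  # single interior extremum: sign of the difference changes exactly twice
  sgn <- sign(diff(areas))
  expect_lte(sum(diff(sgn) != 0), 2L)
})

test_that("generate_dataset writes the documented layout deterministically", {
  dir1 <- tempfile("ds1_"); dir2 <- tempfile("ds2_")
  set.seed(9); generate_dataset(3, "realistic", dir = dir1)
  set.seed(9); generate_dataset(3, "realistic", dir = dir2)
  subs <- list.dirs(dir1, recursive = FALSE)
  expect_length(subs, 3L)
  for (s in subs) {
    expect_true(file.exists(file.path(s, "images.nii.gz")))
    expect_true(file.exists(file.path(s, "masks.nii.gz")))
    tab <- read_indices_csv(file.path(s, "indices.csv"))
    expect_equal(nrow(tab), 20L)
    expect_named(tab, lvq_csv_columns)
  }
  f1 <- file.path(subs[1], "indices.csv")
  f2 <- file.path(list.dirs(dir2, recursive = FALSE)[1], "indices.csv")
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(dir1, dir2), recursive = TRUE)
})

test_that("ED cavity areas of a cohort span the configured radius range", {
  set.seed(101)
  areas <- replicate(50, {
    sp <- sample_phantom_spec("realistic")
    analytic_indices(sp, 0)$area_cav
  })
  # r_endo_ed ~ U(12, 20) -> normalized ED areas roughly pi r^2 / 6400
  expect_lt(min(areas), pi * 14^2 / 6400)
  expect_gt(max(areas), pi * 17^2 / 6400)
})
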