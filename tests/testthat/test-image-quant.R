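# Image generators and their matching measurement operators: round-trip
# recovery of ground truth at pixel / half-percentage-point tolerance.

test_that("drop diameter round trip: rendered disk recovered within 1 px", {
  img <- image_field(make_uniform_binary_disk(256, 100), um_per_px = 50)
  d <- measure_drop_diameter(img)
  expect_lt(abs(d - 10), 0.050)     # 1 px at 50 um/px
  expect_error(measure_drop_diameter(image_field(matrix(0, 64, 64), 50)),
               "no object")
  two <- make_uniform_binary_disk(256, 40)
  two[20:30, 20:30] <- 1
  expect_warning(d2 <- measure_drop_diameter(image_field(two, 50)),
                 "largest")
  expect_lt(abs(d2 - 4), 0.1)
})

test_that("simulated drop frames grow monotonically to D_eq", {
  frames <- simulate_drop_frames(100, 10, n_frames = 6, seed = 3)
  d <- sapply(frames, measure_drop_diameter)
  expect_true(all(diff(d) >= -1e-9))
  expect_lt(abs(d[6] - 10), 0.05)   # 1 px at 25 um/px
  truth <- attr(frames, "truth")
  expect_equal(truth$diameters_mm[6], 10)
  # the S0 = 1 case: footprint stays at the sphere diameter
  d_ideal <- ideal_drop_diameter(100)
  flat <- simulate_drop_frames(100, d_ideal, n_frames = 4, seed = 3)
  dd <- sapply(flat, measure_drop_diameter)
  expect_lt(max(dd) - min(dd), 1e-9)
  expect_error(simulate_drop_frames(100, 2), "no-spreading")
  expect_length(simulate_drop_frames(100, 10, n_frames = 1), 1)
})

test_that("fiber width round trip on a straight bar and simulated fibers", {
  bar <- matrix(0, 200, 120)
  bar[, 36:85] <- 1                  # 50 px wide at 10 um/px = 0.50 mm
  fm <- measure_fiber_profile(image_field(bar, 10), n_points = 10, seed = 2)
  expect_lt(abs(mean(fm$diameters_mm) - 0.5), 0.010)
  # seeded determinism of the sampled point set
  fm2 <- measure_fiber_profile(image_field(bar, 10), n_points = 10, seed = 2)
  expect_identical(fm$diameters_mm, fm2$diameters_mm)
  # resolution floor
  thin <- matrix(0, 50, 20); thin[, 10] <- 1
  expect_error(
    measure_fiber_profile(image_field(thin, 10),
                          cfg = segmentation_config(min_object_area = 1)),
    "3 px")
})

test_that("simulate_print_images: ideal print renders straight exact geometry", {
  tr <- print_job_truth(true_fiber_diameter = 0.5, fiber_waviness_amp = 0,
                        side_jitter_sd = 0, seed = 1)
  imgs <- simulate_print_images(tr, um_per_px = 10)
  fm <- measure_fiber_profile(imgs$fiber, seed = 4)
  expect_equal(fm$n_fibers, 5L)
  expect_lt(abs(mean(fm$diameters_mm) - 0.5), 0.010)          # 1 px
  expect_lt(sd(fm$diameters_mm), 0.011)
  gm <- measure_grid(imgs$grid, cad_side_x = 20, cad_side_y = 20)
  expect_true(all(abs(gm$sides_x - 20) < 0.011))
  expect_true(all(abs(gm$sides_y - 20) < 0.011))
  # seeded determinism of the rendered images
  imgs2 <- simulate_print_images(tr, um_per_px = 10)
  expect_identical(imgs$grid$pixels, imgs2$grid$pixels)
  expect_error(simulate_print_images(
    print_job_truth(true_fiber_diameter = 0.05), um_per_px = 25), "3 px")
})

test_that("jittered grid sides are recovered within 1 px over seeds", {
  errs <- c()
  for (s in 1:12) {
    tr <- print_job_truth(true_fiber_diameter = 0.45,
                          side_jitter_sd = 0.12, seed = s)
    imgs <- simulate_print_images(tr, um_per_px = 25)
    gm <- measure_grid(imgs$grid, cad_side_x = 20, cad_side_y = 20)
    truth <- attr(imgs$grid, "truth")
    errs <- c(errs, abs(gm$sides_x - truth$sides_x),
              abs(gm$sides_y - truth$sides_y))
  }
  expect_lt(max(errs), 0.026)        # 1 px at 25 um/px (+ rounding)
  expect_error(
    measure_grid(image_field(matrix(1, 64, 64), 25)), "no enclosed pores")
})

test_that("granulometry: truth mean within 2% and single-disk within 1 px", {
  pf <- simulate_particle_field(c(100, 150, 200), um_per_px = 2, seed = 5)
  g <- measure_granulometry(pf)
  expect_equal(g$n, 3L)
  expect_lt(abs(g$mean_um - 150) / 150, 0.02)
  one <- simulate_particle_field(147.9, um_per_px = 2, seed = 5)
  g1 <- measure_granulometry(one)
  expect_lt(abs(g1$mean_um - 147.9), 2)   # 1 px at 2 um/px
  empty <- simulate_particle_field(numeric(0), um_per_px = 2)
  ge <- measure_granulometry(empty)
  expect_equal(ge$n, 0L)
  expect_true(ge$empty)
  expect_true(is.na(ge$mean_um))
})

test_that("cell area fraction: binary identity and generator round trip", {
  planes <- simulate_nuclei_planes(c(0.02, 0.05, 0.10), seed = 6)
  truth <- attr(planes, "truth")
  for (p in 1:3) {
    cov <- cell_area_fraction(planes[[p]])
    expect_equal(cov$cell_area_fraction, truth$rendered[p])   # exact, binary
    expect_lt(abs(cov$cell_area_fraction - truth$requested[p]), 0.005)
    # foreground + black fraction is exactly one
    black <- mean(planes[[p]]$pixels == 0)
    expect_equal(cov$cell_area_fraction + black, 1)
  }
  expect_equal(cell_area_fraction(
    image_field(matrix(0, 32, 32), 1))$cell_area_fraction, 0)
  expect_equal(cell_area_fraction(
    image_field(matrix(1, 32, 32), 1),
    segmentation_config("fixed", fixed_value = 128))$cell_area_fraction, 1)
  # blank plane from a zero fraction
  blank <- simulate_nuclei_planes(c(0, 0.05, 0.05), seed = 2)
  expect_equal(sum(blank$top$pixels), 0)
})

test_that("plane-coverage comparison flags sedimentation, not homogeneity", {
  mk <- function(f, lab) structure(list(plane_label = lab,
                                        cell_area_fraction = f),
                                   class = "plane_coverage")
  before <- list(mk(0.05, "top"), mk(0.05, "middle"), mk(0.05, "bottom"))
  same <- compare_plane_coverage(before, before)
  expect_true(same$homogeneous_before && same$homogeneous_after)
  expect_true(all(same$table$abs_diff == 0))
  sediment <- list(mk(0.02, "top"), mk(0.05, "middle"), mk(0.06, "bottom"))
  cmp <- compare_plane_coverage(before, sediment)
  expect_false(cmp$homogeneous_after)
  expect_true(cmp$homogeneous_before)
})

test_that("TIFF writer/reader round trips pixels and scale sidecar", {
  img <- simulate_nuclei_planes(c(0.05, 0.05, 0.05), seed = 9)$middle
  path <- tempfile(fileext = ".tif")
  write_image_tiff(img, path)
  back <- read_image_tiff(path)
  expect_equal(back$pixels, img$pixels)
  expect_equal(back$um_per_px, img$um_per_px)
  expect_equal(back$plane_label, "middle")
})

test_that("measurements are translation invariant", {
  base <- matrix(0, 200, 200)
  a <- base
  a[40:90, 40:90] <- 1               # 51 px square
  b <- base
  b[110:160, 95:145] <- 1
  da <- measure_drop_diameter(image_field(a, 10))
  db <- measure_drop_diameter(image_field(b, 10))
  expect_equal(da, db)
  # scale equivariance: same pixels, doubled um/px, doubled diameter
  d2 <- measure_drop_diameter(image_field(a, 20))
  expect_equal(d2, 2 * da)
})
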