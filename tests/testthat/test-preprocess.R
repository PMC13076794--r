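test_that("read_stack resolves calibration from sidecar or override, else errors", {
  st <- image_stack(array(runif(5 * 2 * 8 * 8), c(5, 2, 8, 8)),
                    pixel_size_um = 0.5, z_step_um = 2, frame_interval_s = 60)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(st, path)
  rt <- read_stack(path)
  expect_identical(dim(rt$data), c(5L, 2L, 8L, 8L))
  expect_equal(rt$pixel_size_um, 0.5)
  # plain TIFF, no sidecar: calibration must come from overrides
  plain <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(list(matrix(runif(64), 8, 8), matrix(runif(64), 8, 8)), plain)
  expect_error(read_stack(plain), "calibration missing")
  ov <- read_stack(plain, pixel_size_um = 1, frame_interval_s = 30, n_z = 2)
  expect_identical(dim(ov$data), c(1L, 2L, 8L, 8L))
  ov2 <- read_stack(plain, pixel_size_um = 1, frame_interval_s = 30, n_z = 1)
  expect_identical(dim(ov2$data), c(2L, 1L, 8L, 8L))
})

test_that("background subtraction removes the frame percentile and is idempotent", {
  # constant frame goes to zero
  st <- image_stack(array(7, c(2, 1, 6, 6)), pixel_size_um = 1)
  out <- subtract_background(st, 10)
  expect_true(all(out$data == 0))
  # sparse signal on flat background: signal pixels recover their amplitude
  fr <- matrix(50, 20, 20)
  fr[5, 5] <- 50 + 300
  st2 <- image_stack(fr, pixel_size_um = 1)
  out2 <- subtract_background(st2, 10)
  expect_equal(out2$data[1, 1, 5, 5], 300)
  expect_true(all(out2$data[1, 1, -5, ] == 0))
  # idempotence on a background-flat frame
  out3 <- subtract_background(out2, 10)
  expect_equal(out3$data, out2$data)
  # one provenance record per call
  expect_length(out3$provenance, 2L)
})

test_that("median filter matches the exhaustive clipped-window oracle", {
  st <- image_stack(matrix(5, 9, 9), pixel_size_um = 1)
  expect_true(all(median_filter(st, 1)$data == 5))
  hot <- matrix(10, 11, 11); hot[6, 6] <- 1000
  sth <- median_filter(image_stack(hot, pixel_size_um = 1), 1)
  expect_true(all(sth$data == 10))
  set.seed(42)
  for (r in c(1L, 2L)) {
    for (i in 1:50) {
      x <- matrix(runif(12 * 14), 12, 14)
      got <- median_filter(image_stack(x, pixel_size_um = 1), r)$data[1, 1, , ]
      expect_equal(unname(got), oracle_median_filter(x, r))
    }
  }
})

test_that("drift correction recovers commanded integer drift exactly", {
  p <- sim_params(seed = 5, field_size_px = c(160, 160), field_size_um = 80,
                  n_frames = 4, extension_rate_um_per_min = 0,
                  retraction_rate_um_per_min = 0, drift_px_per_frame = c(3, 2),
                  noise_model = "none", psf_sigma_px = 0)
  s <- simulate_timelapse(p)
  dc <- correct_drift(s$stack)
  # convention: shift applied to frame t to align it to frame 0
  expect_equal(unname(dc$shifts[, c("dy", "dx")]),
               -s$truth$applied_drift_int)
  # drift-free stack: all shifts zero and pixels unchanged
  s0 <- quick_baseline(seed = 8, ext = 0.5, ret = 0.5, n_frames = 3)
  dc0 <- correct_drift(s0$stack)
  expect_true(all(dc0$shifts == 0))
  expect_equal(dc0$stack$data, s0$stack$data)
  # registering a registered stack a second time adds zero shifts
  dc2 <- correct_drift(dc$stack)
  expect_true(all(dc2$shifts == 0))
})

test_that("max projection reduces Z and preserves content and calibration", {
  a <- array(0, c(1, 2, 4, 4))
  a[1, 1, 1, 1] <- 5; a[1, 2, 3, 3] <- 7
  st <- image_stack(a, pixel_size_um = 0.7)
  pr <- max_project(st)
  expect_identical(dim(pr$data)[2], 1L)
  expect_equal(pr$data[1, 1, 1, 1], 5)
  expect_equal(pr$data[1, 1, 3, 3], 7)
  expect_equal(pr$pixel_size_um, 0.7)
  # Z = 1 is the identity
  st1 <- image_stack(matrix(1:9, 3, 3), pixel_size_um = 1)
  expect_equal(max_project(st1)$data, st1$data)
  # projecting a ball gives (within discretization) its great-circle area
  vol <- ball_volume(10)
  stb <- image_stack(array(vol * 1, c(1, dim(vol))), pixel_size_um = 1)
  area <- sum(max_project(stb)$data[1, 1, , ] > 0)
  expect_equal(area, sum(disc_mask(10)))
})

test_that("make_cell_masks recovers the ground-truth masks and applies QC rules", {
  s <- quick_baseline(seed = 4, ext = 1, ret = 1, n_frames = 6)
  seq1 <- masks_from_stack(s)
  for (t in seq_len(6))
    expect_identical(unname(seq1$masks[[t]]),
                     unname(s$truth$per_frame_true_masks[[t]]))
  # threshold above all intensities errors
  proj <- max_project(s$stack)
  expect_error(make_cell_masks(proj, cell_annotation("c", threshold_value = 2000)),
               "outside the observed ROI intensity range")
  rng_hi <- max(proj$data[1, 1, , ])
  expect_error(make_cell_masks(proj, cell_annotation("c", threshold_value = rng_hi)),
               NA)
  # two nearby cells: only the seeded component is retained
  fr <- matrix(0, 30, 30)
  fr[5:10, 5:10] <- 100     # cell A
  fr[20:25, 20:25] <- 100   # cell B
  st2 <- image_stack(array(fr, c(1, 1, 30, 30)), pixel_size_um = 1)
  got <- make_cell_masks(st2, cell_annotation("c", threshold_value = 50,
                                              seed_yx = c(21, 21)))
  expect_true(got$masks[[1]][21, 21])
  expect_false(any(got$masks[[1]][5:10, 5:10]))
  # masks are subsets of the thresholded ROI and 8-connected
  m <- seq1$masks[[3]]
  expect_true(all(!m | (s$stack$data[3, 1, , ] >= s$truth$threshold_mid)))
  expect_identical(max(mgmorph:::label_mask(m)), 1L)
})

test_that("z-containment QC flags cells touching the z margins", {
  mk <- function(zs) {
    a <- array(0, c(3, 8, 10, 10))
    for (t in 1:3) a[t, zs[[t]], 5, 5] <- 100
    image_stack(a, pixel_size_um = 1)
  }
  ann <- cell_annotation("c", threshold_value = 50)
  expect_true(qc_z_containment(mk(list(4, 4, 5)), ann, margin_slices = 1))
  out <- qc_z_containment(mk(list(4, 1, 4)), ann, margin_slices = 1)
  expect_false(out)
  expect_identical(attr(out, "first_violating_frame"), 2L)
  # margin 2: slice 2 now counts as touching
  expect_false(qc_z_containment(mk(list(4, 4, 2)), ann, margin_slices = 2))
})
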