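test_that("a seeded simulation is bit-identical across runs", {
  p <- sim_params(seed = 7, field_size_px = c(160, 160), field_size_um = 80,
                  n_frames = 4)
  s1 <- simulate_timelapse(p)
  s2 <- simulate_timelapse(p)
  expect_identical(s1$stack$data, s2$stack$data)
  expect_identical(s1$truth$per_frame_true_masks, s2$truth$per_frame_true_masks)
  ps <- sim_params(seed = 7, mode = "static", field_size_px = c(48, 48),
                   field_size_um = 24, n_z = 48, z_step_um = 0.5,
                   n_primary_branches = 3L, branch_length_um = 6)
  expect_identical(simulate_cell_morphology(ps)$volume,
                   simulate_cell_morphology(ps)$volume)
})

test_that("a branchless static cell is a digital ball whose hull is itself", {
  p <- sim_params(seed = 3, mode = "static", field_size_px = c(64, 64),
                  field_size_um = 32, n_z = 64, z_step_um = 0.5,
                  n_primary_branches = 0L, soma_radius_um = 5)
  s <- simulate_cell_morphology(p)
  # soma radius 5 um at 0.5 um/voxel: r = 10 voxels
  expect_lt(abs(s$truth$cell_voxel_count / (4 / 3 * pi * 10^3) - 1), 0.05)
  expect_identical(s$truth$true_territory_voxels, s$truth$cell_voxel_count)
})

test_that("static cells are connected and branches stay in bounds", {
  for (seed in 1:4) {
    p <- sim_params(seed = seed, mode = "static", field_size_px = c(72, 72),
                    field_size_um = 36, n_z = 72, z_step_um = 0.5,
                    n_primary_branches = 4L, branch_length_um = 8)
    s <- simulate_cell_morphology(p)
    lab <- mgmorph:::cpp_label_cc(as.logical(s$volume), dim(s$volume))
    expect_identical(max(lab), 1L)
  }
  # a branch that cannot fit raises an error naming the branch
  expect_error(simulate_cell_morphology(
    sim_params(seed = 1, mode = "static", field_size_px = c(24, 24),
               field_size_um = 12, n_z = 24, z_step_um = 0.5,
               n_primary_branches = 2L, branch_length_um = 30)),
    "branch .* exceeds field bounds")
})

test_that("a frozen cell produces zero PE and PR in every interval", {
  s <- quick_baseline(seed = 2, ext = 0, ret = 0, n_frames = 5)
  expect_identical(s$truth$per_interval_true_pe, rep(0L, 4))
  expect_identical(s$truth$per_interval_true_pr, rep(0L, 4))
  expect_length(s$truth$per_interval_true_pe, 5 - 1)
})

test_that("chemotaxis ground truth follows max(0, d0 - v t) and needs a center", {
  p <- sim_params(seed = 5, mode = "chemotaxis", field_size_px = c(160, 160),
                  field_size_um = 80, n_frames = 10, frame_interval_s = 30,
                  ablation_center_px = c(80, 80),
                  convergence_speed_um_per_min = 3, initial_distance_um = 20,
                  n_primary_branches = 6L, noise_model = "none", psf_sigma_px = 0)
  s <- simulate_timelapse(p)
  expected <- pmax(0, 20 - 3 * (0:9) * 0.5)
  expect_equal(s$truth$true_leading_edge_distance_um, expected)
  # non-increasing until zero, by construction
  expect_true(all(diff(s$truth$true_leading_edge_distance_um) <= 0))
  expect_error(sim_params(seed = 1, mode = "chemotaxis"), "ablation_center_px")
})

test_that("mean true PE per interval matches the Poisson-tip expectation", {
  # retraction off: each tip extends Poisson(q) voxels per frame,
  # q = rate * dt / pixel size; 200 replicate seeds, 4 tips, 5 intervals
  rate <- 0.2
  q <- rate * 1 / 0.5
  n_tips <- 4L
  pe_means <- vapply(1:200, function(seed) {
    s <- quick_baseline(seed = seed, ext = rate, ret = 0, n_frames = 6,
                        field_px = 96, field_um = 48, branches = n_tips,
                        branch_len = 8)
    mean(s$truth$per_interval_true_pe)
  }, 0)
  expected <- n_tips * q
  se <- sd(pe_means) / sqrt(length(pe_means))
  expect_lt(abs(mean(pe_means) - expected), 3 * se + 1e-12)
})

test_that("noiseless unblurred rendering thresholds back to the true mask", {
  s <- quick_baseline(seed = 11, ext = 1, ret = 1, n_frames = 5)
  thr <- s$truth$threshold_mid
  for (t in seq_len(5)) {
    rec <- s$stack$data[t, 1, , ] >= thr
    expect_identical(unname(rec), unname(s$truth$per_frame_true_masks[[t]]))
  }
})

test_that("ground truth records the commanded drift used in rendering", {
  p <- sim_params(seed = 6, field_size_px = c(96, 96), field_size_um = 48,
                  n_frames = 4, n_primary_branches = 3L, branch_length_um = 8,
                  branch_prob = 0, extension_rate_um_per_min = 0,
                  retraction_rate_um_per_min = 0,
                  drift_px_per_frame = c(1.5, -0.5),
                  noise_model = "none", psf_sigma_px = 0)
  s <- simulate_timelapse(p)
  expect_equal(s$truth$applied_drift,
               outer(0:3, c(1.5, -0.5)))
  expect_equal(s$truth$applied_drift_int, round(outer(0:3, c(1.5, -0.5))))
  # true masks are recorded before the drift shift
  expect_identical(s$truth$per_frame_true_masks[[1]],
                   s$truth$per_frame_true_masks[[4]])
})

test_that("simulation round-trips through TIFF, JSON and YAML sidecars", {
  s <- quick_baseline(seed = 3, n_frames = 3, field_px = 64, field_um = 32)
  p <- sim_params(seed = 3, field_size_px = c(64, 64), field_size_um = 32)
  dir <- withr::local_tempdir()
  write_simulation(s, p, dir)
  st <- read_stack(file.path(dir, "stack.tif"))
  expect_identical(dim(st$data), dim(s$stack$data))
  expect_equal(st$pixel_size_um, 0.5)
  expect_equal(st$frame_interval_s, 60)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$per_interval_true_pe, s$truth$per_interval_true_pe)
  prm <- yaml::read_yaml(file.path(dir, "params.yaml"))
  expect_equal(prm$seed, 3)
})
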