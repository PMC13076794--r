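test_that("otsu threshold matches exhaustive between-class-variance maximization", {
  set.seed(8)
  for (i in 1:100) {
    x <- c(rnorm(400, 60, runif(1, 5, 15)), rnorm(250, 180, runif(1, 10, 25)))
    x <- pmax(x, 0)
    expect_equal(otsu_threshold(x), oracle_otsu(x))
  }
  expect_error(otsu_threshold(rep(3, 10)), "constant")
})

test_that("otsu agrees with the EBImage reference on scaled images", {
  set.seed(9)
  for (i in 1:10) {
    # overlapping classes so the between-class-variance maximum is unique
    img <- matrix(pmin(1, pmax(0, c(rnorm(600, 0.25, 0.1), rnorm(424, 0.7, 0.12)))),
                  32, 32)
    ours <- otsu_threshold(img)
    ref <- EBImage::otsu(img, range = range(img), levels = 256)
    expect_lt(abs(ours - ref), 2 * (max(img) - min(img)) / 256 + 1e-12)
  }
})

test_that("segmentation finds well-separated cells and filters speckle", {
  vol <- array(0, c(12, 40, 40))
  vol[4:8, 5:12, 5:12] <- 100     # cell 1: 320 voxels
  vol[4:8, 25:32, 25:32] <- 100   # cell 2
  lab <- segment_cells(vol, morpho_params(min_object_voxels = 50))
  expect_identical(attr(lab, "n_cells"), 2L)
  # 50-voxel speckles die under min_object_voxels = 200
  spk <- array(0, c(10, 30, 30))
  spk[2:3, 2:6, 2:6] <- 100
  spk[7:8, 20:24, 20:24] <- 100
  lab2 <- segment_cells(spk, morpho_params(min_object_voxels = 200))
  expect_identical(attr(lab2, "n_cells"), 0L)
  expect_error(segment_cells(array(0, c(4, 4, 4))), "all-zero")
  # label count is non-increasing in min_object_voxels and otsu_scale
  set.seed(2)
  noisy <- array(runif(10 * 24 * 24)^4 * 200, c(10, 24, 24))
  counts_sz <- vapply(c(1, 5, 20, 80), function(mv)
    attr(segment_cells(noisy, morpho_params(min_object_voxels = mv)), "n_cells"),
    0L)
  expect_true(all(diff(counts_sz) <= 0))
  # graded constant-intensity blobs drop out whole as the threshold scales up
  graded <- array(0, c(8, 36, 36))
  graded[3:5, 3:7, 3:7] <- 60
  graded[3:5, 15:19, 15:19] <- 120
  graded[3:5, 28:32, 28:32] <- 240
  counts_sc <- vapply(c(0.5, 1, 1.5), function(sc)
    attr(segment_cells(graded, morpho_params(otsu_scale = sc,
                                             min_object_voxels = 1)), "n_cells"),
    0L)
  expect_true(all(diff(counts_sc) <= 0))
})

test_that("border-touching cells are excluded by exhaustive face contact", {
  vol <- array(0, c(10, 30, 30))
  vol[4:6, 10:14, 10:14] <- 100          # centered: retained
  vol[1:3, 22:26, 22:26] <- 100          # touches z = 0 face: removed
  lab <- segment_cells(vol, morpho_params(min_object_voxels = 10))
  fl <- exclude_border_cells(lab, 1)
  expect_identical(length(unique(fl[fl > 0])), 1L)
  expect_true(all(fl[, 10:14, 10:14] > 0 | vol[, 10:14, 10:14] == 0))
  # oracle: brute-force face-contact scan
  d <- dim(lab)
  bad <- c()
  for (l in unique(lab[lab > 0])) {
    vox <- which(lab == l, arr.ind = TRUE)
    if (any(vox == 1) || any(vox[, 1] == d[1]) || any(vox[, 2] == d[2]) ||
        any(vox[, 3] == d[3])) bad <- c(bad, l)
  }
  expect_identical(sort(attr(fl, "removed_labels")), sort(as.integer(bad)))
})

test_that("convex-hull territory satisfies the ball, tetrahedron and hull properties", {
  r <- 16
  vol <- ball_volume(r)
  terr <- cell_territory(vol, c(1, 1, 1))
  expect_lt(abs(terr / (4 / 3 * pi * r^3) - 1), 0.05)
  # regular tetrahedron with unit edge: V = 1/(6*sqrt(2))
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  expect_equal(as.numeric(cell_territory(tet)), 1 / (6 * sqrt(2)),
               tolerance = 1e-12)
  # adding an interior voxel leaves the hull volume unchanged
  v2 <- vol
  v2[dim(vol)[1] %/% 2, dim(vol)[2] %/% 2, dim(vol)[3] %/% 2] <- TRUE
  expect_equal(as.numeric(cell_territory(v2)), as.numeric(terr))
  # hull monotonicity: adding any voxel never decreases the volume
  set.seed(4)
  for (i in 1:10) {
    v3 <- vol
    v3[sample(dim(vol)[1], 1), sample(dim(vol)[2], 1), sample(dim(vol)[3], 1)] <- TRUE
    expect_gte(as.numeric(cell_territory(v3)), as.numeric(terr) - 1e-9)
  }
  # translation and 90-degree rotation invariance
  shifted <- array(FALSE, dim(vol) + c(3, 0, 0))
  shifted[3 + seq_len(dim(vol)[1]), , ] <- vol
  expect_equal(as.numeric(cell_territory(shifted)), as.numeric(terr))
  expect_equal(as.numeric(cell_territory(aperm(vol, c(2, 1, 3)))),
               as.numeric(terr))
  # degenerate planar cell: 2D hull area times z-step, flagged
  plane <- array(FALSE, c(5, 20, 20)); plane[3, 5:15, 5:15] <- TRUE
  tp <- cell_territory(plane, c(2, 1, 1))
  expect_true(attr(tp, "degenerate"))
  expect_equal(as.numeric(tp), 10 * 10 * 2)
})

test_that("skeleton metrics recover rod, Y and phantom branch topology", {
  rod <- array(FALSE, c(3, 3, 14)); rod[2, 2, 3:12] <- TRUE
  sk <- skeleton_metrics(rod)
  expect_identical(sk$branch_points, 0L)
  expect_identical(sk$end_points, 2L)
  expect_equal(sk$total_length_um, 9)
  y <- array(FALSE, c(3, 21, 21)); y[2, 11, 3:11] <- TRUE
  for (k in 1:7) { y[2, 11 - k, 11 + k] <- TRUE; y[2, 11 + k, 11 + k] <- TRUE }
  sk2 <- skeleton_metrics(y)
  expect_identical(sk2$branch_points, 1L)
  expect_identical(sk2$end_points, 3L)
  # simulated cell with k primaries and no sub-branching: end points = k (+/- 1)
  for (k in c(4L, 6L)) {
    p <- sim_params(seed = 40 + k, mode = "static", field_size_px = c(80, 80),
                    field_size_um = 40, n_z = 80, z_step_um = 0.5,
                    n_primary_branches = k, branch_length_um = 12,
                    branch_prob = 0, max_branch_depth = 1L, soma_radius_um = 3)
    s <- simulate_cell_morphology(p)
    sk3 <- skeleton_metrics(s$volume, rep(0.5, 3), prune_um = 3)
    expect_lte(abs(sk3$end_points - k), 1L)
  }
})

test_that("deramified phantoms score lower territory and fewer end points", {
  mk <- function(seed, branches, len) simulate_cell_morphology(
    sim_params(seed = seed, mode = "static", field_size_px = c(80, 80),
               field_size_um = 40, n_z = 80, z_step_um = 0.5,
               n_primary_branches = branches, branch_length_um = len,
               branch_prob = 0, max_branch_depth = 1L, soma_radius_um = 3))
  for (seed in 1:3) {
    ram <- mk(seed, 6L, 12)
    der <- mk(seed, 3L, 5)
    expect_gt(as.numeric(cell_territory(ram$volume, rep(0.5, 3))),
              as.numeric(cell_territory(der$volume, rep(0.5, 3))))
    expect_gt(skeleton_metrics(ram$volume, rep(0.5, 3), prune_um = 3)$end_points,
              skeleton_metrics(der$volume, rep(0.5, 3), prune_um = 3)$end_points)
  }
})

test_that("spot detection counts planted somata and merges close pairs", {
  plant <- function(centers, d = c(16, 50, 50), amp = 100) {
    vol <- array(0, d)
    for (i in seq_len(nrow(centers))) vol[centers[i, 1], centers[i, 2], centers[i, 3]] <- amp
    vol
  }
  pars <- morpho_params(spot_min_distance_um = 6, spot_min_intensity = 1)
  v1 <- plant(rbind(c(8, 10, 10), c(8, 10, 40), c(8, 40, 25)))
  expect_identical(spot_density(v1, pars, c(1, 1, 1))$count, 3L)
  # two somata closer than the minimum separation count once
  v2 <- plant(rbind(c(8, 20, 20), c(8, 20, 23)))
  expect_identical(spot_density(v2, pars, c(1, 1, 1))$count, 1L)
  # randomized placements at separation >= 2x min distance: exact counts
  set.seed(14)
  err <- 0L; total <- 0L
  for (rep in 1:40) {
    k <- sample(2:5, 1)
    repeat {
      ctr <- cbind(sample(4:13, k, TRUE), sample(5:46, k, TRUE), sample(5:46, k, TRUE))
      dmat <- as.matrix(dist(ctr))
      if (k == 1 || min(dmat[upper.tri(dmat)]) >= 12) break
    }
    got <- spot_density(plant(ctr), pars, c(1, 1, 1))$count
    err <- err + abs(got - k)
    total <- total + k
  }
  expect_lte(err / total, 0.02)
})
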