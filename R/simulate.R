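#' Parameters of the synthetic microglia generator
#'
#' Defines a seeded phantom of one ramified microglial cell (or, in
#' chemotaxis mode, a ring of processes converging on a lesion) on a pixel
#' lattice, together with the acquisition model used to render it. Defaults
#' mirror a typical two-photon surveillance acquisition: a 512 x 512 pixel
#' frame over a 258 um square field (0.504 um/px isotropic), 2 um z-steps
#' and one frame per minute; chemotaxis acquisitions use 30 s frames.
#'
#' The phantom has a bright soma and dimmer 1-voxel-wide processes grown as
#' persistent lattice random walks (26-connected in 3D, 8-connected in 2D),
#' which is what makes a single automatic threshold unreliable on the
#' rendered images and motivates the per-cell manual threshold of the
#' analysis pipeline. In baseline mode each branch tip independently extends
#' or retracts; the expected pixel turnover per tip and frame is
#' `rate * (frame_interval / 60) / pixel_size` in each direction. In
#' chemotaxis mode `n_primary_branches` processes start on a circle of
#' radius `initial_distance_um` around `ablation_center_px` and extend
#' radially inward at `convergence_speed_um_per_min`.
#'
#' @param seed RNG seed; the same seed gives a bit-identical simulation.
#' @param field_size_px `(Y, X)` frame size in pixels (square).
#' @param field_size_um lateral field size in um; pixel size is
#'   `field_size_um / field_size_px[1]` and must be isotropic.
#' @param n_z number of z-slices (1 = single plane).
#' @param z_step_um axial step.
#' @param frame_interval_s frame interval (s).
#' @param n_frames number of time points.
#' @param soma_radius_um soma radius.
#' @param n_primary_branches primary processes leaving the soma.
#' @param branch_length_um target length of each primary process.
#' @param branch_step_um growth step length (one voxel is painted per step).
#' @param branch_prob per-step probability of spawning a side branch.
#' @param max_branch_depth maximum branching depth (1 = primaries only).
#' @param extension_rate_um_per_min,retraction_rate_um_per_min baseline tip
#'   speeds (>= 0).
#' @param mode `"baseline"`, `"chemotaxis"` or `"static"`.
#' @param ablation_center_px `(y, x)` 0-based lesion center (chemotaxis).
#' @param convergence_speed_um_per_min inward tip speed (chemotaxis).
#' @param initial_distance_um initial tip distance to the lesion.
#' @param drift_px_per_frame `(dy, dx)` lateral drift added per frame
#'   (real-valued; applied cumulatively at rendering).
#' @param soma_intensity,process_intensity,background_mean painted
#'   intensities (a.u.); `process_intensity` must be below `soma_intensity`
#'   and above `background_mean`.
#' @param noise_model `"none"`, `"gaussian"`, `"poisson"` or `"mixed"`
#'   (Poisson shot noise then Gaussian read noise).
#' @param read_noise_sd Gaussian read-noise s.d. (a.u.).
#' @param photons_per_au photon yield per intensity unit for shot noise.
#' @param psf_sigma_px lateral Gaussian PSF sigma (0 disables blurring).
#' @param direction_jitter s.d. of the per-step direction perturbation of
#'   the growth random walk.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(seed = 1L,
                       field_size_px = c(512L, 512L),
                       field_size_um = 258,
                       n_z = 1L,
                       z_step_um = 2,
                       frame_interval_s = 60,
                       n_frames = 10L,
                       soma_radius_um = 5,
                       n_primary_branches = 6L,
                       branch_length_um = 20,
                       branch_step_um = NULL,
                       branch_prob = 0.15,
                       max_branch_depth = 2L,
                       extension_rate_um_per_min = 1.5,
                       retraction_rate_um_per_min = 1.5,
                       mode = c("baseline", "chemotaxis", "static"),
                       ablation_center_px = NULL,
                       convergence_speed_um_per_min = 2,
                       initial_distance_um = 30,
                       drift_px_per_frame = c(0, 0),
                       soma_intensity = 1000,
                       process_intensity = 400,
                       background_mean = 100,
                       noise_model = c("mixed", "gaussian", "poisson", "none"),
                       read_noise_sd = 5,
                       photons_per_au = 1,
                       psf_sigma_px = 1,
                       direction_jitter = 0.25) {
  mode <- match.arg(mode)
  noise_model <- match.arg(noise_model)
  if (field_size_px[1] != field_size_px[2])
    stop("field must be square (isotropic pixel size)")
  pixel_size_um <- field_size_um / field_size_px[1]
  if (is.null(branch_step_um)) branch_step_um <- pixel_size_um
  if (process_intensity >= soma_intensity)
    stop("process_intensity must be below soma_intensity")
  if (process_intensity <= background_mean)
    stop("process_intensity must exceed background_mean")
  if (branch_prob < 0 || branch_prob > 1) stop("branch_prob must be in [0, 1]")
  if (extension_rate_um_per_min < 0 || retraction_rate_um_per_min < 0 ||
      convergence_speed_um_per_min < 0)
    stop("rates must be >= 0")
  if (mode == "chemotaxis" && is.null(ablation_center_px))
    stop("chemotaxis mode requires ablation_center_px")
  structure(as.list(environment()), class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf("<sim_params> %s, seed %d: %dx%d px (%.3f um/px), Z=%d, T=%d\n",
              x$mode, x$seed, x$field_size_px[1], x$field_size_px[2],
              x$pixel_size_um, x$n_z, x$n_frames))
  invisible(x)
}

with_sim_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) c(1, 0, 0) else v / n
}

# 26 (or, in-plane, 8) lattice offsets, (z,y,x)
lattice_offsets <- function(flat) {
  o <- as.matrix(expand.grid(z = -1:1, y = -1:1, x = -1:1))
  o <- o[rowSums(abs(o)) > 0, ]
  if (flat) o <- o[o[, 1] == 0, ]
  o
}

# pick the free lattice step best aligned with `dir`; NULL if none in bounds
pick_step <- function(pos, dir, occupied, dims, offs) {
  sc <- offs %*% dir / sqrt(rowSums(offs^2))
  for (k in order(sc, decreasing = TRUE)) {
    cand <- pos + offs[k, ]
    if (any(cand < 1) || any(cand > dims)) next
    key <- voxel_key(cand, dims)
    if (!is.null(occupied[[key]])) next
    return(list(pos = cand, key = key))
  }
  NULL
}

voxel_key <- function(v, dims) {
  as.character((v[1] - 1) + dims[1] * ((v[2] - 1) + dims[2] * (v[3] - 1)))
}

# digital ball (ellipsoid in voxel units when z-spacing differs)
soma_voxels <- function(center, r_um, pixel_size_um, z_step_um, dims) {
  rl <- r_um / pixel_size_um
  rz <- if (dims[1] > 1) r_um / z_step_um else 0
  zr <- if (dims[1] > 1) floor(-rz):ceiling(rz) else 0L
  yr <- floor(-rl):ceiling(rl)
  g <- as.matrix(expand.grid(z = zr, y = yr, x = yr))
  d2 <- (if (rz > 0) (g[, 1] / rz)^2 else 0) + (g[, 2] / rl)^2 + (g[, 3] / rl)^2
  g <- g[d2 <= 1, , drop = FALSE]
  v <- sweep(g, 2, center, `+`)
  v[v[, 1] >= 1 & v[, 1] <= dims[1] &
    v[, 2] >= 1 & v[, 2] <= dims[2] &
    v[, 3] >= 1 & v[, 3] <= dims[3], , drop = FALSE]
}

# grow the branch system; returns list(paths, occupied) or errors when a
# branch leaves the field
grow_branches <- function(p, center, dims, occupied) {
  offs <- lattice_offsets(dims[1] == 1)
  n_steps <- max(1L, round(p$branch_length_um / p$branch_step_um))
  r_px <- p$soma_radius_um / p$pixel_size_um
  paths <- list()
  queue <- list()
  for (i in seq_len(p$n_primary_branches)) {
    ang <- (i - 0.5) * 2 * pi / p$n_primary_branches + runif(1, -0.2, 0.2)
    dz <- if (dims[1] > 1) runif(1, -0.3, 0.3) else 0
    dir <- unit3(c(dz, sin(ang), cos(ang)))
    start <- center + round(dir * c(if (dims[1] > 1) r_px * p$pixel_size_um / p$z_step_um else 0, r_px, r_px))
    queue[[length(queue) + 1L]] <- list(start = start, dir = dir, steps = n_steps,
                                        depth = 1L, id = i)
  }
  qi <- 1L
  while (qi <= length(queue)) {
    b <- queue[[qi]]; qi <- qi + 1L
    pos <- pmin(pmax(b$start, 1), dims)
    if (!all(b$start == pos))
      stop("branch ", b$id, " exceeds field bounds at its root")
    dir <- b$dir
    # paint the root so the branch is connected to its parent structure
    coords <- matrix(pos, 1, 3)
    if (is.null(occupied[[voxel_key(pos, dims)]]))
      assign(voxel_key(pos, dims), TRUE, occupied)
    for (s in seq_len(b$steps)) {
      cand <- pos + offs[which.max(offs %*% dir / sqrt(rowSums(offs^2))), ]
      if (any(cand < 1) || any(cand > dims))
        stop("branch ", b$id, " exceeds field bounds")
      st <- pick_step(pos, dir, occupied, dims, offs)
      if (is.null(st)) break
      pos <- st$pos
      occupied[[st$key]] <- TRUE
      coords <- rbind(coords, pos)
      dir <- unit3(dir + rnorm(3, sd = p$direction_jitter) *
                     c(if (dims[1] > 1) 1 else 0, 1, 1))
      if (b$depth < p$max_branch_depth && runif(1) < p$branch_prob &&
          s > 2) {
        sub_dir <- unit3(dir + rnorm(3, sd = 1) * c(if (dims[1] > 1) 1 else 0, 1, 1))
        queue[[length(queue) + 1L]] <- list(start = pos, dir = sub_dir,
                                            steps = max(2L, (b$steps - s) %/% 2L),
                                            depth = b$depth + 1L,
                                            id = b$id)
      }
    }
    if (nrow(coords) > 0)
      paths[[length(paths) + 1L]] <- list(coords = coords, dir = dir,
                                          depth = b$depth, id = b$id)
  }
  list(paths = paths, occupied = occupied)
}

paint_mask <- function(soma, paths, dims) {
  m <- array(FALSE, dims)
  m[soma] <- TRUE
  for (b in paths) if (nrow(b$coords) > 0) m[b$coords] <- TRUE
  m
}

#' Simulate a static ramified cell with known territory
#'
#' Builds a connected phantom (digital soma ball plus persistent lattice
#' random-walk branches) for validating the 3D morphometrics: the returned
#' ground truth includes the cell's convex-hull voxel count computed
#' exhaustively (every grid voxel tested against the hull facets).
#'
#' @param params a [sim_params()] with `mode = "static"`.
#' @return List with `volume` (logical `Z x Y x X`), and `truth`: a list with
#'   `true_territory_voxels`, `n_tips` (tip count of the grown branch system),
#'   `soma_center`, `soma_voxel_count`, `cell_voxel_count`.
#' @export
simulate_cell_morphology <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (params$mode != "static") stop("simulate_cell_morphology needs mode = 'static'")
  with_sim_seed(params$seed, {
    dims <- c(params$n_z, params$field_size_px[1], params$field_size_px[2])
    center <- pmax(1, round(dims / 2))
    soma <- soma_voxels(center, params$soma_radius_um, params$pixel_size_um,
                        params$z_step_um, dims)
    if (nrow(soma) == 0 ||
        any(center - params$soma_radius_um / params$pixel_size_um < 0) )
      stop("field too small for the soma")
    occupied <- new.env(hash = TRUE, parent = emptyenv())
    for (i in seq_len(nrow(soma)))
      assign(voxel_key(soma[i, ], dims), TRUE, occupied)
    gb <- grow_branches(params, center, dims, occupied)
    vol <- paint_mask(soma, gb$paths, dims)
    vox <- which(vol, arr.ind = TRUE)
    hull <- hull_facets(which(boundary_voxels(vol), arr.ind = TRUE))
    terr <- if (isTRUE(hull$degenerate)) sum(vol) else {
      bb_lo <- apply(vox, 2, min); bb_hi <- apply(vox, 2, max)
      grid <- as.matrix(expand.grid(z = bb_lo[1]:bb_hi[1], y = bb_lo[2]:bb_hi[2],
                                    x = bb_lo[3]:bb_hi[3]))
      sum(points_in_hull(grid, hull, tol = 1e-7))
    }
    list(volume = vol,
         truth = list(true_territory_voxels = terr,
                      n_tips = length(gb$paths),
                      soma_center = center,
                      soma_voxel_count = nrow(soma),
                      cell_voxel_count = sum(vol)))
  })
}

# acquisition model: paint intensities, blur laterally, shift by the
# cumulative drift, add noise
render_frame <- function(mask3d, soma_mask, p, cum_drift) {
  dims <- dim(mask3d)
  img <- array(p$background_mean, dims)
  img[mask3d] <- p$process_intensity
  img[soma_mask] <- p$soma_intensity
  for (z in seq_len(dims[1])) {
    sl <- img[z, , ]
    if (p$psf_sigma_px > 0) sl <- cpp_gauss_blur(sl, p$psf_sigma_px)
    if (any(cum_drift != 0)) {
      if (all(cum_drift == round(cum_drift)))
        sl <- shift_slice(sl, cum_drift[1], cum_drift[2])
      else
        sl <- shift_slice_subpixel(sl, cum_drift[1], cum_drift[2])
    }
    img[z, , ] <- sl
  }
  if (p$noise_model %in% c("poisson", "mixed"))
    img[] <- rpois(length(img), pmax(img, 0) * p$photons_per_au) / p$photons_per_au
  if (p$noise_model %in% c("gaussian", "mixed"))
    img[] <- img + rnorm(length(img), sd = p$read_noise_sd)
  pmax(img, 0)
}

#' Simulate a microglia time-lapse with ground truth
#'
#' Baseline mode: every branch tip of the phantom moves each frame by the
#' net of competing extension and retraction step counts, each drawn as
#' Poisson with mean `rate * (frame_interval / 60) / pixel_size` (one voxel
#' is added or removed per step). With the retraction rate at zero the
#' expected number of extension pixels per tip and frame is therefore
#' exactly the extension mean. Chemotaxis mode: `n_primary_branches`
#' processes start `initial_distance_um` from the ablation center, evenly
#' spaced in angle (at the centers of an `n_primary_branches`-sector
#' partition), and extend radially inward at the convergence speed, so the
#' true leading-edge distance is `max(0, d0 - v * t)`.
#'
#' Rendering applies, in order: intensity painting (soma above processes
#' above background), lateral PSF blur, the commanded cumulative drift
#' shift, and noise. Ground truth records the unrendered, undrifted masks
#' (maximum-projected to 2D), per-interval PE/PR pixel counts derived from
#' them, the commanded real-valued and integer-rounded drift per frame, and
#' in chemotaxis mode the analytic leading-edge distance per frame.
#'
#' @param params a [sim_params()] with mode `"baseline"` or `"chemotaxis"`.
#' @return List with `stack` (an [image_stack()]) and `truth` (class
#'   `sim_truth`): `per_frame_true_masks`, `per_interval_true_pe`,
#'   `per_interval_true_pr`, `applied_drift`, `applied_drift_int`,
#'   `true_leading_edge_distance_um` (chemotaxis), `n_tips`, `threshold_mid`
#'   (the mid-intensity threshold that recovers the true mask on noiseless,
#'   unblurred renderings).
#' @export
simulate_timelapse <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (!params$mode %in% c("baseline", "chemotaxis"))
    stop("simulate_timelapse needs mode 'baseline' or 'chemotaxis'")
  if (params$n_frames < 2) stop("n_frames must be >= 2")
  with_sim_seed(params$seed, {
    if (params$mode == "baseline") sim_baseline(params) else sim_chemotaxis(params)
  })
}

sim_baseline <- function(p) {
  dims <- c(p$n_z, p$field_size_px[1], p$field_size_px[2])
  center <- pmax(1, round(dims / 2))
  soma <- soma_voxels(center, p$soma_radius_um, p$pixel_size_um, p$z_step_um, dims)
  occupied <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(soma))) assign(voxel_key(soma[i, ], dims), TRUE, occupied)
  gb <- grow_branches(p, center, dims, occupied)
  paths <- gb$paths
  occupied <- gb$occupied
  soma_mask <- array(FALSE, dims); soma_mask[soma] <- TRUE
  offs <- lattice_offsets(dims[1] == 1)
  dt_min <- p$frame_interval_s / 60
  q_ext <- p$extension_rate_um_per_min * dt_min / p$pixel_size_um
  q_ret <- p$retraction_rate_um_per_min * dt_min / p$pixel_size_um
  draw_steps <- function(q) rpois(1, q)  # mean q steps per tip and frame
  masks2d <- vector("list", p$n_frames)
  stack_data <- array(0, c(p$n_frames, dims[1], dims[2], dims[3]))
  drift <- matrix(0, p$n_frames, 2)
  for (t in seq_len(p$n_frames)) {
    if (t > 1) {
      for (bi in seq_along(paths)) {
        b <- paths[[bi]]
        # net tip displacement this frame: extension and retraction compete
        net <- draw_steps(q_ext) - draw_steps(q_ret)
        if (net > 0) {
          for (s in seq_len(net)) {
            pos <- b$coords[nrow(b$coords), ]
            st <- pick_step(pos, b$dir, occupied, dims, offs)
            if (is.null(st)) break
            b$coords <- rbind(b$coords, st$pos)
            assign(st$key, TRUE, occupied)
            b$dir <- unit3(b$dir + rnorm(3, sd = p$direction_jitter) *
                             c(if (dims[1] > 1) 1 else 0, 1, 1))
          }
        } else if (net < 0) {
          for (s in seq_len(-net)) {
            if (nrow(b$coords) <= 1) break
            last <- b$coords[nrow(b$coords), ]
            rm(list = voxel_key(last, dims), envir = occupied)
            b$coords <- b$coords[-nrow(b$coords), , drop = FALSE]
          }
        }
        paths[[bi]] <- b
      }
      drift[t, ] <- drift[t - 1, ] + p$drift_px_per_frame
    }
    m3 <- paint_mask(soma, paths, dims)
    masks2d[[t]] <- project_any(m3)
    stack_data[t, , , ] <- render_frame(m3, soma_mask, p, drift[t, ])
  }
  finalize_sim(p, stack_data, masks2d, drift, lead = NULL,
               n_tips = length(paths))
}

sim_chemotaxis <- function(p) {
  dims <- c(p$n_z, p$field_size_px[1], p$field_size_px[2])
  ctr <- p$ablation_center_px  # (y, x), 0-based
  k <- p$n_primary_branches
  d0_px <- p$initial_distance_um / p$pixel_size_um
  v_px <- p$convergence_speed_um_per_min * (p$frame_interval_s / 60) / p$pixel_size_um
  angles <- ((seq_len(k) - 0.5) / k) * 2 * pi
  zmid <- max(1L, as.integer(ceiling(dims[1] / 2)))
  soma_r_px <- (p$soma_radius_um / 2) / p$pixel_size_um
  soma_off <- d0_px + soma_r_px + 3  # inner soma edge stays behind the tips
  soma_all <- NULL
  for (a in angles) {
    sc <- c(zmid, round(ctr[1] + 1 - sin(a) * soma_off),
            round(ctr[2] + 1 + cos(a) * soma_off))
    soma_all <- rbind(soma_all,
                      soma_voxels(sc, p$soma_radius_um / 2, p$pixel_size_um,
                                  p$z_step_um, dims))
  }
  soma_mask <- array(FALSE, dims)
  if (!is.null(soma_all) && nrow(soma_all) > 0) soma_mask[soma_all] <- TRUE
  masks2d <- vector("list", p$n_frames)
  stack_data <- array(0, c(p$n_frames, dims[1], dims[2], dims[3]))
  drift <- matrix(0, p$n_frames, 2)
  lead <- numeric(p$n_frames)
  for (t in seq_len(p$n_frames)) {
    d_t <- max(0, d0_px - v_px * (t - 1))
    lead[t] <- d_t * p$pixel_size_um
    m3 <- array(FALSE, dims)
    m3[soma_mask] <- TRUE
    for (a in angles) {
      # rasterize the radial process from the soma inward to the current tip
      rr <- seq(soma_off, d_t, by = -0.25)
      if (length(rr) == 0) rr <- d_t
      yy <- pmin(dims[2], pmax(1, round(ctr[1] + 1 - sin(a) * rr)))
      xx <- pmin(dims[3], pmax(1, round(ctr[2] + 1 + cos(a) * rr)))
      m3[cbind(zmid, yy, xx)] <- TRUE
    }
    if (t > 1) drift[t, ] <- drift[t - 1, ] + p$drift_px_per_frame
    masks2d[[t]] <- project_any(m3)
    stack_data[t, , , ] <- render_frame(m3, soma_mask, p, drift[t, ])
  }
  finalize_sim(p, stack_data, masks2d, drift, lead = lead, n_tips = k)
}

project_any <- function(m3) {
  if (dim(m3)[1] == 1) {
    m <- m3[1, , ]
    dim(m) <- dim(m3)[2:3]
    m
  } else apply(m3, c(2, 3), any)
}

finalize_sim <- function(p, stack_data, masks2d, drift, lead, n_tips) {
  T <- p$n_frames
  pe <- pr <- integer(max(T - 1, 0))
  for (t in seq_len(T - 1)) {
    d <- compute_pe_pr(masks2d[[t]], masks2d[[t + 1]])
    pe[t] <- d[1]; pr[t] <- d[2]
  }
  stack <- image_stack(stack_data, pixel_size_um = p$pixel_size_um,
                       z_step_um = p$z_step_um,
                       frame_interval_s = p$frame_interval_s,
                       channel_label = "synthetic-GFP")
  truth <- structure(list(per_frame_true_masks = masks2d,
                          per_interval_true_pe = pe,
                          per_interval_true_pr = pr,
                          applied_drift = drift,
                          applied_drift_int = round(drift),
                          true_leading_edge_distance_um = lead,
                          n_tips = n_tips,
                          threshold_mid = (p$background_mean + p$process_intensity) / 2),
                     class = "sim_truth")
  list(stack = stack, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d frames, %d tips; mean PE %.1f, mean PR %.1f px/interval\n",
              length(x$per_frame_true_masks), x$n_tips,
              mean(x$per_interval_true_pe), mean(x$per_interval_true_pr)))
  invisible(x)
}

#' Default parameter sets for a two-genotype synthetic cohort
#'
#' Control cells are ramified and motile; knockout cells emulate the
#' deramified, hypomotile phenotype with half the branch count, shorter
#' processes and halved extension/retraction (or convergence) rates.
#'
#' @param genotype `"control"` or `"knockout"`.
#' @param seed RNG seed for this cell.
#' @param ... overrides passed on to [sim_params()].
#' @return A [sim_params()].
#' @export
cohort_params <- function(genotype = c("control", "knockout"), seed = 1L, ...) {
  genotype <- match.arg(genotype)
  base <- list(seed = seed,
               n_primary_branches = 6L, branch_length_um = 20,
               extension_rate_um_per_min = 1.5, retraction_rate_um_per_min = 1.5,
               convergence_speed_um_per_min = 2)
  if (genotype == "knockout") {
    base$n_primary_branches <- 3L
    base$branch_length_um <- 8
    base$extension_rate_um_per_min <- 0.75
    base$retraction_rate_um_per_min <- 0.75
    base$convergence_speed_um_per_min <- 0.5
  }
  do.call(sim_params, utils::modifyList(base, list(...)))
}

#' Write a simulation to disk
#'
#' Writes the rendered stack as multi-page TIFF with its JSON calibration
#' sidecar, the ground-truth masks as a second multi-page TIFF (0/1), the
#' scalar ground-truth series as JSON, and the resolved parameters as YAML.
#'
#' @param sim a [simulate_timelapse()] result.
#' @param params the [sim_params()] used.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, params, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stack(sim$stack, file.path(dir, "stack.tif"))
  masks <- lapply(sim$truth$per_frame_true_masks, function(m) m * 1)
  tiff::writeTIFF(masks, file.path(dir, "true_masks.tif"), bits.per.sample = 8L)
  tr <- sim$truth
  tr$per_frame_true_masks <- NULL
  jsonlite::write_json(unclass(tr), file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  pl <- unclass(params)
  pl$mode <- as.character(pl$mode)
  yaml::write_yaml(pl, file.path(dir, "params.yaml"))
  invisible(dir)
}
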