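#' Per-frame percentile background subtraction
#'
#' Subtracts, from every frame (all z-slices of a time point jointly), the
#' given intensity percentile of that frame, clipping at zero. The percentile
#' estimator is used because background level drifts slowly over a time-lapse
#' while the cell occupies only a small area fraction; the default 10th
#' percentile sits safely below typical process intensities.
#'
#' @param stack an [image_stack()].
#' @param percentile percentile in `[0, 100)`.
#' @return The background-subtracted [image_stack()], provenance appended.
#' @export
subtract_background <- function(stack, percentile = 10) {
  stopifnot(is.numeric(percentile), length(percentile) == 1L,
            percentile >= 0, percentile < 100)
  for (t in seq_len(n_frames(stack))) {
    fr <- stack$data[t, , , , drop = FALSE]
    bg <- quantile(fr, percentile / 100, names = FALSE, type = 7)
    stack$data[t, , , ] <- pmax(fr - bg, 0)
  }
  add_provenance(stack, "subtract_background", list(percentile = percentile))
}

#' Per-slice 2D median filter
#'
#' Applies an exact median filter with a square window of side
#' `2 * radius_px + 1` to every (t, z) slice. Windows are clipped at the image
#' border (the median is taken over the pixels actually inside the image).
#'
#' @param stack an [image_stack()].
#' @param radius_px window radius in pixels (integer >= 1).
#' @return The filtered [image_stack()], provenance appended.
#' @export
median_filter <- function(stack, radius_px = 1L) {
  stopifnot(radius_px >= 1)
  d <- dim(stack$data)
  for (t in seq_len(d[1]))
    for (z in seq_len(d[2]))
      stack$data[t, z, , ] <- cpp_median_filter(stack$data[t, z, , ],
                                                as.integer(radius_px))
  add_provenance(stack, "median_filter", list(radius_px = radius_px))
}

# integer circular cross-correlation shift between two equally sized arrays,
# via FFT; returns the shift to apply to `moving` to best align it to `ref`
xc_shift <- function(ref, moving) {
  d <- dim(ref)
  if (is.null(d)) d <- length(ref)
  F1 <- fft(ref)
  F2 <- fft(moving)
  cc <- Re(fft(F1 * Conj(F2), inverse = TRUE))
  peak <- which.max(cc) - 1L
  idx <- integer(length(d))
  rem <- peak
  for (k in seq_along(d)) {
    idx[k] <- rem %% d[k]
    rem <- rem %/% d[k]
  }
  # fold to signed shifts
  ifelse(idx > d / 2, idx - d, idx)
}

shift_slice <- function(m, dy, dx) {
  # integer translation with zero fill
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(0, ny, nx)
  ys <- seq_len(ny) - dy; xs <- seq_len(nx) - dx
  okY <- ys >= 1 & ys <= ny; okX <- xs >= 1 & xs <= nx
  out[okY, okX] <- m[ys[okY], xs[okX]]
  out
}

shift_slice_subpixel <- function(m, dy, dx) {
  # bilinear interpolation, zero outside
  iy <- floor(dy); ix <- floor(dx)
  fy <- dy - iy; fx <- dx - ix
  m00 <- shift_slice(m, iy, ix)
  m10 <- shift_slice(m, iy + 1, ix)
  m01 <- shift_slice(m, iy, ix + 1)
  m11 <- shift_slice(m, iy + 1, ix + 1)
  (1 - fy) * (1 - fx) * m00 + fy * (1 - fx) * m10 +
    (1 - fy) * fx * m01 + fy * fx * m11
}

#' Correct lateral and axial drift of a time-lapse
#'
#' Registers every frame to the first frame: lateral shifts are estimated by
#' maximizing the cross-correlation of maximum-intensity projections, axial
#' shifts by cross-correlating z-profiles (slice sums). Shifts are estimated
#' at integer precision (which makes recovery of an integer drift exact) and
#' reported in the convention "shift applied to frame t to align it to frame
#' 0": a frame whose content drifted by +d gets shift -d.
#'
#' @param stack an [image_stack()] with at least 2 frames.
#' @return A list with `stack` (registered) and `shifts`, a `T x 3` matrix of
#'   (dz, dy, dx) applied to each frame (first row is zero). Frames with zero
#'   variance reuse the previous frame's shift and are flagged in provenance.
#' @export
correct_drift <- function(stack) {
  d <- dim(stack$data)
  if (d[1] < 2) stop("drift correction needs at least 2 frames")
  ref_proj <- apply(frame_array(stack, 1), c(2, 3), max)
  ref_zpro <- apply(frame_array(stack, 1), 1, sum)
  shifts <- matrix(0, d[1], 3, dimnames = list(NULL, c("dz", "dy", "dx")))
  flat <- integer(0)
  for (t in seq_len(d[1])[-1]) {
    fr <- frame_array(stack, t)
    if (var(as.vector(fr)) == 0) {
      shifts[t, ] <- shifts[t - 1, ]
      flat <- c(flat, t)
    } else {
      proj <- apply(fr, c(2, 3), max)
      s_lat <- xc_shift(ref_proj, proj)
      s_z <- if (d[2] > 1) xc_shift(ref_zpro, apply(fr, 1, sum)) else 0L
      shifts[t, ] <- c(s_z, s_lat)
    }
    dz <- shifts[t, 1]; dy <- shifts[t, 2]; dx <- shifts[t, 3]
    new <- array(0, d[2:4])
    for (z in seq_len(d[2])) {
      zs <- z - dz
      if (zs >= 1 && zs <= d[2])
        new[z, , ] <- shift_slice(fr[zs, , ], dy, dx)
    }
    stack$data[t, , , ] <- new
  }
  stack <- add_provenance(stack, "correct_drift",
                          list(shifts = shifts, zero_variance_frames = flat))
  list(stack = stack, shifts = shifts)
}

#' Maximum-intensity projection over z
#'
#' @param stack an [image_stack()].
#' @return An [image_stack()] with Z = 1; calibration preserved, provenance
#'   appended. With Z = 1 already, the data are unchanged.
#' @export
max_project <- function(stack) {
  d <- dim(stack$data)
  if (d[2] > 1) {
    proj <- apply(stack$data, c(1, 3, 4), max)
    dim(proj) <- c(d[1], 1L, d[3], d[4])
    stack$data <- proj
  }
  add_provenance(stack, "max_project", list())
}

#' Per-cell annotation
#'
#' Records the operator-chosen parameters for one cell of a time-lapse: the
#' manual intensity threshold (peripheral processes are dimmer than somata,
#' so a single automatic threshold is unreliable), the ROI crop, identity and
#' grouping, and optionally a seed pixel marking the cell at frame 0 and the
#' laser-ablation center for chemotaxis events.
#'
#' @param cell_id,animal_id identifiers.
#' @param genotype_group group label, e.g. `"control"` or `"knockout"`.
#' @param threshold_value manual intensity threshold; foreground is
#'   `intensity >= threshold_value` (ties are foreground).
#' @param roi_bounds `(y0, y1, x0, x1)` half-open 0-based pixel box, i.e.
#'   rows `y0..y1-1` and columns `x0..x1-1` (0-based).
#' @param seed_yx optional `(y, x)` 0-based pixel on the cell at frame 0;
#'   when absent, the largest frame-0 component is taken as the cell.
#' @param ablation_center_yx optional `(y, x)` 0-based ablation center (may
#'   be fractional), in uncropped frame coordinates.
#' @return An object of class `cell_annotation`.
#' @export
cell_annotation <- function(cell_id, animal_id = NA_character_,
                            genotype_group = NA_character_,
                            threshold_value = NULL, roi_bounds = NULL,
                            seed_yx = NULL, ablation_center_yx = NULL) {
  if (!is.null(roi_bounds)) {
    stopifnot(length(roi_bounds) == 4)
    if (roi_bounds[1] >= roi_bounds[2] || roi_bounds[3] >= roi_bounds[4])
      stop("roi_bounds must satisfy y0 < y1 and x0 < x1")
  }
  structure(list(cell_id = cell_id, animal_id = animal_id,
                 genotype_group = genotype_group,
                 threshold_value = threshold_value, roi_bounds = roi_bounds,
                 seed_yx = seed_yx, ablation_center_yx = ablation_center_yx,
                 z_contained = NA),
            class = "cell_annotation")
}

#' Read cell annotations from a YAML sidecar
#'
#' The file holds a list `cells:` of records with fields matching
#' [cell_annotation()] arguments.
#'
#' @param path YAML file.
#' @return A list of `cell_annotation` objects.
#' @export
read_annotations <- function(path) {
  y <- yaml::read_yaml(path)
  cells <- if (!is.null(y$cells)) y$cells else y
  lapply(cells, function(cc)
    cell_annotation(cell_id = cc$cell_id,
                    animal_id = if (is.null(cc$animal_id)) NA_character_ else cc$animal_id,
                    genotype_group = if (is.null(cc$genotype_group)) NA_character_ else cc$genotype_group,
                    threshold_value = cc$threshold_value,
                    roi_bounds = unlist(cc$roi_bounds),
                    seed_yx = unlist(cc$seed_yx),
                    ablation_center_yx = unlist(cc$ablation_center_yx)))
}

#' Otsu threshold on a 256-bin histogram
#'
#' Exhaustively maximizes the between-class variance over 256 candidate
#' levels after min-max scaling; the returned level is on the original
#' intensity scale. Offered as a fallback where no manual threshold exists;
#' [make_cell_masks()] never substitutes it silently.
#'
#' @param x numeric vector or array of intensities.
#' @param n_bins histogram resolution.
#' @return The threshold level (foreground is `x >= level`).
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  lo <- min(x); hi <- max(x)
  if (hi <= lo) stop("cannot threshold a constant image")
  h <- tabulate(pmin(n_bins, floor((x - lo) / (hi - lo) * n_bins) + 1L), n_bins)
  p <- h / sum(h)
  mids <- lo + (seq_len(n_bins) - 0.5) / n_bins * (hi - lo)
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  bcv <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- -Inf
  k <- which.max(bcv)
  # level = upper edge of the chosen bin: foreground strictly above it
  lo + k / n_bins * (hi - lo)
}

#' Threshold a projected stack into a per-cell mask sequence
#'
#' Crops the annotation ROI, thresholds every frame at the cell's manual
#' threshold (`intensity >= threshold`), and keeps, per frame, only the
#' 8-connected component(s) overlapping the tracked cell: at frame 0 the
#' component containing the annotation seed (or the largest component when no
#' seed is given), afterwards the components overlapping the previous
#' retained mask. Frames with no overlap are flagged empty and kept so that
#' interval series stay aligned.
#'
#' @param stack a projected [image_stack()] (Z = 1).
#' @param ann a [cell_annotation()] with `threshold_value` (and `roi_bounds`;
#'   absent bounds take the full frame).
#' @return An object of class `cell_mask_sequence`: list with `masks`
#'   (list of logical Y x X matrices), `empty` (logical per frame),
#'   calibration fields, the annotation and a provenance list.
#' @export
make_cell_masks <- function(stack, ann) {
  d <- dim(stack$data)
  if (d[2] != 1) stop("make_cell_masks expects a projected stack (Z = 1); ",
                      "call max_project() first")
  if (is.null(ann$threshold_value)) stop("annotation has no threshold_value")
  rb <- ann$roi_bounds
  if (is.null(rb)) rb <- c(0, d[3], 0, d[4])
  if (rb[1] < 0 || rb[2] > d[3] || rb[3] < 0 || rb[4] > d[4])
    stop("roi_bounds outside frame")
  ys <- (rb[1] + 1):rb[2]
  xs <- (rb[3] + 1):rb[4]
  thr <- ann$threshold_value
  roi0 <- stack$data[1, 1, ys, xs]
  rng <- range(roi0)
  if (thr < rng[1] || thr > rng[2])
    stop("threshold ", thr, " outside the observed ROI intensity range [",
         rng[1], ", ", rng[2], "]")
  masks <- vector("list", d[1])
  empty <- logical(d[1])
  prev <- NULL
  for (t in seq_len(d[1])) {
    fg <- stack$data[t, 1, ys, xs] >= thr
    lab <- label_mask(fg)
    if (t == 1L) {
      if (!any(fg)) stop("cell not found at threshold")
      keep <- if (!is.null(ann$seed_yx)) {
        sy <- ann$seed_yx[1] - rb[1] + 1L
        sx <- ann$seed_yx[2] - rb[3] + 1L
        l <- lab[sy, sx]
        if (l == 0L) stop("cell not found at threshold (seed not foreground)")
        l
      } else {
        which.max(tabulate(lab[lab > 0L]))
      }
      m <- lab == keep
    } else {
      ids <- unique(lab[lab > 0L & prev])
      m <- lab %in% ids & lab > 0L
      dim(m) <- dim(lab)
    }
    empty[t] <- !any(m)
    masks[[t]] <- m
    if (!empty[t]) prev <- m
  }
  structure(list(cell_id = ann$cell_id, masks = masks, empty = empty,
                 pixel_size_um = stack$pixel_size_um,
                 frame_interval_s = stack$frame_interval_s,
                 annotation = ann,
                 provenance = c(stack$provenance,
                                list(list(step = "make_cell_masks",
                                          params = list(threshold = thr,
                                                        roi_bounds = rb))))),
            class = "cell_mask_sequence")
}

#' @export
print.cell_mask_sequence <- function(x, ...) {
  cat(sprintf("<cell_mask_sequence> cell %s: %d frames of %d x %d px, %d empty\n",
              x$cell_id, length(x$masks), nrow(x$masks[[1]]), ncol(x$masks[[1]]),
              sum(x$empty)))
  invisible(x)
}

# 8-connected labeling of a 2D logical matrix
label_mask <- function(m) {
  lab <- cpp_label_cc(as.logical(m), c(1L, nrow(m), ncol(m)))
  dim(lab) <- dim(m)
  lab
}

#' Z-containment quality control
#'
#' A cell passes QC only if, at every frame, none of its above-threshold
#' voxels lies within `margin_slices` of the top or bottom z-slice; cells
#' drifting (even partly) out of the acquired volume would otherwise lose
#' pixels to partial-volume truncation and bias the motility metrics.
#'
#' @param stack an unprojected [image_stack()].
#' @param ann a [cell_annotation()] with `threshold_value` (and optionally
#'   `roi_bounds`, applied laterally).
#' @param margin_slices slices at each end of the z-range counted as
#'   "touching" (>= 1).
#' @return `TRUE`/`FALSE`; on failure the attribute `first_violating_frame`
#'   holds the earliest offending frame index (1-based).
#' @export
qc_z_containment <- function(stack, ann, margin_slices = 1L) {
  d <- dim(stack$data)
  stopifnot(margin_slices >= 1, 2 * margin_slices < d[2])
  rb <- ann$roi_bounds
  if (is.null(rb)) rb <- c(0, d[3], 0, d[4])
  ys <- (rb[1] + 1):rb[2]
  xs <- (rb[3] + 1):rb[4]
  zbad <- c(seq_len(margin_slices), d[2] - seq_len(margin_slices) + 1L)
  for (t in seq_len(d[1])) {
    edge <- stack$data[t, zbad, ys, xs]
    if (any(edge >= ann$threshold_value)) {
      out <- FALSE
      attr(out, "first_violating_frame") <- t
      return(out)
    }
  }
  TRUE
}
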