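#' Parameters for static 3D morphometrics
#'
#' @param otsu_scale multiplier applied to the Otsu level of the stack
#'   histogram before thresholding (typically 0.5-1.5).
#' @param min_object_voxels connected components smaller than this are
#'   discarded as noise (typically 200-500 for 40x confocal stacks).
#' @param border_margin_vox margin (in voxels) from any volume face within
#'   which a touching cell is excluded.
#' @param spot_min_distance_um minimum separation between detected somata.
#' @param spot_min_intensity minimum (smoothed) intensity of a soma peak.
#' @param size_percentile_bounds optional `c(lo, hi)` percentiles of the
#'   per-image component-size distribution; components outside are dropped
#'   (the largest/smallest cells are defined per image, not by fixed voxel
#'   limits).
#' @return An object of class `morpho_params`.
#' @export
morpho_params <- function(otsu_scale = 1, min_object_voxels = 300L,
                          border_margin_vox = 1L, spot_min_distance_um = 10,
                          spot_min_intensity = 0,
                          size_percentile_bounds = NULL) {
  stopifnot(otsu_scale > 0, min_object_voxels >= 0, border_margin_vox >= 0)
  structure(list(otsu_scale = otsu_scale,
                 min_object_voxels = as.integer(min_object_voxels),
                 border_margin_vox = as.integer(border_margin_vox),
                 spot_min_distance_um = spot_min_distance_um,
                 spot_min_intensity = spot_min_intensity,
                 size_percentile_bounds = size_percentile_bounds),
            class = "morpho_params")
}

#' Segment cells in a 3D confocal stack
#'
#' Thresholds the volume at `otsu_scale` times the Otsu level of its 256-bin
#' histogram, labels 26-connected components, and removes components smaller
#' than `min_object_voxels` (and outside the optional per-image size
#' percentile bounds).
#'
#' @param volume 3D numeric array `Z x Y x X` (single channel).
#' @param params a [morpho_params()].
#' @return Integer label array of the volume's shape (labels renumbered
#'   1..n); attributes `threshold` and `n_cells`.
#' @export
segment_cells <- function(volume, params = morpho_params()) {
  if (all(volume == 0)) stop("cannot segment an all-zero stack")
  thr <- params$otsu_scale * otsu_threshold(volume)
  lab <- cpp_label_cc(as.logical(volume >= thr), dim(volume))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= params$min_object_voxels)
  if (!is.null(params$size_percentile_bounds) && length(keep)) {
    b <- quantile(sizes[keep], params$size_percentile_bounds / 100, names = FALSE)
    keep <- keep[sizes[keep] >= b[1] & sizes[keep] <= b[2]]
  }
  out <- array(0L, dim(volume))
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  attr(out, "threshold") <- thr
  attr(out, "n_cells") <- length(keep)
  out
}

#' Exclude cells touching the volume border
#'
#' Cells cut off at the stack faces have truncated morphology; any label with
#' a voxel within `margin` slices/rows/columns of any face (margin 1 = the
#' outermost layer itself) is removed.
#'
#' @param labels integer label array from [segment_cells()].
#' @param margin border margin in voxels (>= 1).
#' @return The filtered label array (labels renumbered); attribute
#'   `removed_labels` lists the original labels dropped.
#' @export
exclude_border_cells <- function(labels, margin = 1L) {
  stopifnot(margin >= 1)
  d <- dim(labels)
  border <- c(labels[c(seq_len(margin), d[1] - seq_len(margin) + 1L), , ],
              labels[, c(seq_len(margin), d[2] - seq_len(margin) + 1L), ],
              labels[, , c(seq_len(margin), d[3] - seq_len(margin) + 1L)])
  bad <- sort(unique(border[border > 0L]))
  keep <- setdiff(sort(unique(labels[labels > 0L])), bad)
  out <- array(0L, d)
  for (i in seq_along(keep)) out[labels == keep[i]] <- i
  attr(out, "removed_labels") <- bad
  out
}

#' Convex-hull territory of a cell
#'
#' The tissue domain a ramified cell occupies, measured as the volume of the
#' 3D convex hull of its voxel centers (in physical coordinates). Degenerate
#' (coplanar) cells fall back to the 2D hull area times the z-step and are
#' flagged.
#'
#' @param cell logical 3D array `Z x Y x X`, or an `n x 3` matrix of (z, y, x)
#'   voxel indices.
#' @param spacing_um `(z, y, x)` voxel spacing in micrometers.
#' @return Territory in um^3; attribute `degenerate` is `TRUE` for the planar
#'   fallback.
#' @export
cell_territory <- function(cell, spacing_um = c(1, 1, 1)) {
  pts <- if (is.array(cell) && length(dim(cell)) == 3L)
    which(boundary_voxels(cell), arr.ind = TRUE) else as.matrix(cell)
  if (nrow(pts) < 4) stop("territory needs at least 4 voxels")
  phys <- sweep(pts, 2, spacing_um, `*`)
  h <- cpp_hull3d(phys)
  if (isTRUE(h$degenerate)) {
    # planar cell: 2D hull area in the plane of largest spread, times z-step
    v <- apply(phys, 2, var)
    drop_ax <- which.min(v)
    p2 <- phys[, -drop_ax, drop = FALSE]
    ch <- chull(p2)
    xy <- p2[ch, , drop = FALSE]
    n <- nrow(xy)
    area <- abs(sum(xy[, 1] * xy[c(2:n, 1), 2] - xy[c(2:n, 1), 1] * xy[, 2])) / 2
    out <- area * spacing_um[drop_ax]
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- h$volume
  attr(out, "degenerate") <- FALSE
  out
}

# hull facet planes for exhaustive point-in-hull checks (used by the
# simulator's ground-truth territory)
hull_facets <- function(pts) {
  cpp_hull3d(as.matrix(pts))
}

# voxels with at least one 6-neighbor outside the set (or on the array face);
# their convex hull equals the hull of the whole set
boundary_voxels <- function(vol) {
  d <- dim(vol)
  interior <- vol
  for (ax in 1:3) {
    for (s in c(-1L, 1L)) {
      shifted <- array(FALSE, d)
      idx_src <- lapply(d, seq_len)
      idx_dst <- idx_src
      n <- d[ax]
      if (s == 1L) { idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- 1:(n - 1L) }
      else { idx_dst[[ax]] <- 1:(n - 1L); idx_src[[ax]] <- 2:n }
      shifted <- do.call(`[<-`, c(list(shifted), idx_dst,
                                  list(do.call(`[`, c(list(vol), idx_src)))))
      interior <- interior & shifted
    }
  }
  vol & !interior
}

points_in_hull <- function(pts, hull, tol = 1e-7) {
  if (isTRUE(hull$degenerate)) return(rep(FALSE, nrow(pts)))
  inside <- rep(TRUE, nrow(pts))
  for (f in seq_len(nrow(hull$normals))) {
    s <- pts %*% hull$normals[f, ] - hull$offsets[f]
    inside <- inside & (s <= tol)
  }
  inside
}

#' Skeleton-based branching metrics of a cell
#'
#' Thins the cell to a 1-voxel-wide skeleton by sequential topology-preserving
#' (simple-point) erosion with endpoint preservation, then counts branch
#' points (skeleton voxels with >= 3 neighbors, 26-connectivity) and end
#' points (exactly 1 neighbor), and measures total skeleton length as the
#' physical length of the minimum spanning tree of the skeleton's
#' 26-adjacency graph. Anisotropic volumes are resampled to an isotropic grid
#' (nearest neighbor along z) before thinning.
#'
#' Thinning a thick body (the soma) leaves short spurious side spurs; chains
#' from an end point to the nearest junction shorter than `prune_um` are
#' therefore pruned (iteratively) before counting. Set `prune_um` below the
#' shortest genuine process length.
#'
#' @param cell logical 3D array `Z x Y x X`.
#' @param spacing_um `(z, y, x)` voxel spacing in micrometers.
#' @param prune_um spur-pruning length threshold (0 disables pruning).
#' @return List with `branch_points`, `end_points`, `total_length_um`,
#'   `skeleton` (logical array on the analysis grid).
#' @export
skeleton_metrics <- function(cell, spacing_um = c(1, 1, 1), prune_um = 0) {
  stopifnot(length(dim(cell)) == 3L)
  sp <- spacing_um
  if (abs(sp[1] - sp[2]) > 1e-9 * sp[2]) {
    # resample z to the lateral spacing
    nz_new <- max(2L, round(dim(cell)[1] * sp[1] / sp[2]))
    zi <- pmin(dim(cell)[1], pmax(1L, round(seq(1, dim(cell)[1], length.out = nz_new))))
    cell <- cell[zi, , , drop = FALSE]
    sp <- c(sp[2], sp[2], sp[3])
  }
  sk <- cpp_thin3d(as.logical(cell), dim(cell))
  dim(sk) <- dim(cell)
  g <- skeleton_graph(sk, sp)
  if (prune_um > 0 && g$n > 0) {
    repeat {
      drop <- prune_spurs_once(g, prune_um)
      if (length(drop) == 0) break
      keep <- setdiff(seq_len(g$n), drop)
      sk[g$vox[drop, , drop = FALSE]] <- FALSE
      g <- skeleton_graph(sk, sp)
    }
  }
  total <- 0
  if (!is.null(g$edges) && nrow(g$edges) > 0) {
    ig <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
    igraph::E(ig)$weight <- g$w
    total <- sum(igraph::E(igraph::mst(ig))$weight)
  }
  list(branch_points = sum(g$deg >= 3L), end_points = sum(g$deg == 1L),
       total_length_um = total, skeleton = sk)
}

# 26-adjacency graph of skeleton voxels with physical edge lengths
skeleton_graph <- function(sk, sp) {
  d <- dim(sk)
  vox <- which(sk, arr.ind = TRUE)
  n <- nrow(vox)
  if (n == 0) return(list(n = 0L, vox = vox, deg = integer(0),
                          edges = NULL, w = NULL, adj = list()))
  key <- (vox[, 1] - 1) + d[1] * ((vox[, 2] - 1) + d[2] * (vox[, 3] - 1))
  lut <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n)) assign(as.character(key[i]), i, lut)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  deg <- integer(n)
  edges <- NULL
  w <- NULL
  adj <- vector("list", n)
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(vox, 2, offs[k, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    nbkey <- (nb[, 1] - 1) + d[1] * ((nb[, 2] - 1) + d[2] * (nb[, 3] - 1))
    j <- rep(NA_integer_, n)
    for (i in which(ok)) {
      v <- lut[[as.character(nbkey[i])]]
      if (!is.null(v)) j[i] <- v
    }
    hit <- which(!is.na(j))
    deg[hit] <- deg[hit] + 1L
    len <- sqrt(sum((offs[k, ] * sp)^2))
    for (i in hit) adj[[i]] <- rbind(adj[[i]], c(j[i], len))
    up <- hit[j[hit] > hit]
    if (length(up)) {
      edges <- rbind(edges, cbind(up, j[up]))
      w <- c(w, rep(len, length(up)))
    }
  }
  list(n = n, vox = vox, deg = deg, edges = edges, w = w, adj = adj)
}

# indices of voxels on endpoint-to-junction chains shorter than prune_um
prune_spurs_once <- function(g, prune_um) {
  drop <- integer(0)
  for (e in which(g$deg == 1L)) {
    path <- e
    len <- 0
    prev <- -1L
    cur <- e
    repeat {
      nbrs <- g$adj[[cur]]
      nxt <- nbrs[nbrs[, 1] != prev, , drop = FALSE]
      if (nrow(nxt) != 1) break  # junction reached via current voxel, or dead end
      prev <- cur
      cur <- nxt[1, 1]
      len <- len + nxt[1, 2]
      if (g$deg[cur] >= 3L) {
        if (len < prune_um) drop <- c(drop, path)
        break
      }
      if (g$deg[cur] == 1L) break  # isolated chain: keep whole component
      path <- c(path, cur)
      if (len >= prune_um) break
    }
  }
  unique(drop)
}

#' Morphometrics of every segmented cell
#'
#' @param labels label array from [segment_cells()] /
#'   [exclude_border_cells()].
#' @param spacing_um `(z, y, x)` voxel spacing.
#' @param prune_um skeleton spur-pruning threshold, see [skeleton_metrics()].
#' @return `data.frame` with one row per cell: voxel count, territory
#'   (um^3), skeleton branch/end points and total length (um).
#' @export
cell_morphology_table <- function(labels, spacing_um = c(1, 1, 1),
                                  prune_um = 0) {
  ids <- sort(unique(labels[labels > 0L]))
  rows <- lapply(ids, function(i) {
    cell <- labels == i
    dim(cell) <- dim(labels)
    terr <- tryCatch(as.numeric(cell_territory(cell, spacing_um)),
                     error = function(e) NA_real_)
    sk <- skeleton_metrics(cell, spacing_um, prune_um = prune_um)
    data.frame(cell_id = i, voxel_count = sum(cell), territory_um3 = terr,
               skeleton_branch_points = sk$branch_points,
               skeleton_end_points = sk$end_points,
               skeleton_total_length_um = sk$total_length_um)
  })
  do.call(rbind, rows)
}

#' Spot-based cell density
#'
#' Detects somata as local intensity maxima of the (Gaussian-smoothed)
#' nucleus/soma channel, keeps peaks above `spot_min_intensity`, and greedily
#' suppresses peaks closer than `spot_min_distance_um` to a brighter one.
#' Density is the count divided by the calibrated volume.
#'
#' @param volume 3D numeric array `Z x Y x X`.
#' @param params a [morpho_params()].
#' @param spacing_um `(z, y, x)` voxel spacing.
#' @param smooth_sigma_px lateral Gaussian sigma applied per slice before
#'   peak detection (0 disables).
#' @return List with `count`, `density_per_mm3`, `centers` (n x 3 voxel
#'   indices).
#' @export
spot_density <- function(volume, params = morpho_params(),
                         spacing_um = c(1, 1, 1), smooth_sigma_px = 1) {
  d <- dim(volume)
  sm <- volume
  if (smooth_sigma_px > 0)
    for (z in seq_len(d[1])) sm[z, , ] <- cpp_gauss_blur(sm[z, , ], smooth_sigma_px)
  # local maxima over the 3x3x3 neighborhood
  is_max <- array(TRUE, d)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (!dz && !dy && !dx) next
    shifted <- array(-Inf, d)
    zs <- seq_len(d[1]) - dz; ys <- seq_len(d[2]) - dy; xs <- seq_len(d[3]) - dx
    okz <- zs >= 1 & zs <= d[1]; oky <- ys >= 1 & ys <= d[2]; okx <- xs >= 1 & xs <= d[3]
    shifted[okz, oky, okx] <- sm[zs[okz], ys[oky], xs[okx]]
    is_max <- is_max & (sm >= shifted)
  }
  cand <- which(is_max & sm >= params$spot_min_intensity & sm > min(sm),
                arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(list(count = 0L, density_per_mm3 = 0, centers = cand))
  vals <- sm[cand]
  ord <- order(vals, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  phys <- sweep(cand, 2, spacing_um, `*`)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    dd <- sqrt(rowSums(sweep(phys[keep, , drop = FALSE], 2, phys[i, ], `-`)^2))
    if (all(dd >= params$spot_min_distance_um)) keep[i] <- TRUE
  }
  centers <- cand[keep, , drop = FALSE]
  vol_mm3 <- prod(d * spacing_um) * 1e-9
  list(count = sum(keep), density_per_mm3 = sum(keep) / vol_mm3,
       centers = centers)
}
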