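#' Assign foreground pixels to radial sectors around an ablation center
#'
#' Partitions the plane into `n_sectors` equal angular sectors around the
#' manually placed ablation center. Angles follow the mathematical
#' convention, counter-clockwise from the +x axis, with the image y-axis
#' pointing down (so "counter-clockwise" on screen is clockwise in array
#' indices): `theta = atan2(-(y - cy), x - cx)` normalized to `[0, 2*pi)`,
#' and a pixel lands in sector `floor(n_sectors * theta / (2*pi))`. Sector 0
#' starts at the +x axis.
#'
#' @param mask logical matrix.
#' @param center `(y, x)` center, 0-based pixel coordinates (fractional
#'   allowed); positions at most one field-of-view outside the frame are
#'   tolerated.
#' @param n_sectors number of equal sectors (default 36).
#' @return Integer matrix of the mask's shape: sector index (0-based) for
#'   foreground pixels, `NA` elsewhere.
#' @export
assign_sectors <- function(mask, center, n_sectors = 36L) {
  stopifnot(n_sectors >= 1)
  ny <- nrow(mask); nx <- ncol(mask)
  if (center[1] < -ny || center[1] > 2 * ny || center[2] < -nx || center[2] > 2 * nx)
    stop("ablation center too far outside the frame")
  idx <- which(mask, arr.ind = TRUE)
  out <- matrix(NA_integer_, ny, nx)
  if (nrow(idx) == 0) return(out)
  dy <- (idx[, 1] - 1) - center[1]
  dx <- (idx[, 2] - 1) - center[2]
  theta <- atan2(-dy, dx) %% (2 * pi)
  s <- pmin(as.integer(floor(n_sectors * theta / (2 * pi))), n_sectors - 1L)
  out[idx] <- s
  out
}

#' Per-sector leading-edge distance to the ablation center
#'
#' The leading edge of the chemotactic response in a sector is taken as the
#' foreground pixel of that sector nearest to the ablation center; the
#' distance is Euclidean between pixel centers, scaled to micrometers.
#' Sectors containing no foreground are reported missing rather than imputed
#' (imputing at the crop radius would make the result depend on crop size).
#'
#' @param mask logical matrix.
#' @param center `(y, x)` 0-based ablation center.
#' @param n_sectors number of sectors.
#' @param pixel_size_um lateral pixel size.
#' @param sectors optional precomputed [assign_sectors()] matrix.
#' @return Numeric vector of length `n_sectors` (um), `NA` where empty.
#' @export
leading_edge_distance <- function(mask, center, n_sectors = 36L,
                                  pixel_size_um = 1, sectors = NULL) {
  if (is.null(sectors)) sectors <- assign_sectors(mask, center, n_sectors)
  idx <- which(mask, arr.ind = TRUE)
  out <- rep(NA_real_, n_sectors)
  if (nrow(idx) == 0) return(out)
  d <- sqrt(((idx[, 1] - 1) - center[1])^2 + ((idx[, 2] - 1) - center[2])^2)
  s <- sectors[idx]
  mins <- tapply(d, factor(s, levels = 0:(n_sectors - 1L)), min)
  out[!is.na(mins)] <- mins[!is.na(mins)] * pixel_size_um
  out
}

#' Chemotaxis response curve of one ablation event
#'
#' For every frame of a masked time-lapse (maximum-projected and manually
#' thresholded, as for surveillance), computes per-sector leading-edge
#' distances and their per-frame summary across responding (non-missing)
#' sectors. As processes converge on the lesion the summary distance
#' declines toward zero.
#'
#' @param masks list of logical matrices (frames), or a `cell_mask_sequence`.
#' @param center `(y, x)` 0-based ablation center.
#' @param n_sectors number of radial sectors (default 36).
#' @param pixel_size_um,frame_interval_s calibration (taken from the mask
#'   sequence when one is supplied).
#' @param summary_stat `"mean"` (default) or `"median"` over responding
#'   sectors; the choice is recorded in the event.
#' @param event_id,animal_id,genotype_group identifiers carried through.
#' @return An object of class `chemotaxis_event` with `sector_distance_um`
#'   (T x n_sectors), `mean_distance_um`, `responding_sectors`, `times_s`,
#'   `auc_um_s` (see [chemotaxis_auc()]) and metadata. Frames where all
#'   sectors are missing yield a missing summary and are flagged.
#' @export
response_curve <- function(masks, center, n_sectors = 36L,
                           pixel_size_um = NULL, frame_interval_s = NULL,
                           summary_stat = c("mean", "median"),
                           event_id = NA, animal_id = NA, genotype_group = NA) {
  summary_stat <- match.arg(summary_stat)
  if (inherits(masks, "cell_mask_sequence")) {
    if (is.null(pixel_size_um)) pixel_size_um <- masks$pixel_size_um
    if (is.null(frame_interval_s)) frame_interval_s <- masks$frame_interval_s
    masks <- masks$masks
  }
  if (is.null(pixel_size_um) || is.null(frame_interval_s))
    stop("pixel_size_um and frame_interval_s are required")
  T <- length(masks)
  if (T < 2) stop("response curve needs at least 2 frames")
  sd_um <- matrix(NA_real_, T, n_sectors)
  for (t in seq_len(T))
    sd_um[t, ] <- leading_edge_distance(masks[[t]], center, n_sectors,
                                        pixel_size_um)
  responding <- rowSums(!is.na(sd_um))
  f <- if (summary_stat == "mean") mean else median
  mean_d <- apply(sd_um, 1, function(r)
    if (all(is.na(r))) NA_real_ else f(r, na.rm = TRUE))
  ev <- structure(list(event_id = event_id, animal_id = animal_id,
                       genotype_group = genotype_group, center_px = center,
                       n_sectors = n_sectors, sector_distance_um = sd_um,
                       mean_distance_um = mean_d,
                       responding_sectors = responding,
                       times_s = (seq_len(T) - 1) * frame_interval_s,
                       frame_interval_s = frame_interval_s,
                       summary_stat = summary_stat,
                       all_missing_frames = which(is.na(mean_d))),
                  class = "chemotaxis_event")
  ev$auc_um_s <- chemotaxis_auc(ev)
  ev
}

#' @export
print.chemotaxis_event <- function(x, ...) {
  cat(sprintf("<chemotaxis_event> %s (%s/%s): %d frames, %d sectors\n",
              x$event_id, x$animal_id, x$genotype_group,
              length(x$mean_distance_um), x$n_sectors))
  cat(sprintf("  %s distance %.2f -> %.2f um, AUC %.1f um*s\n", x$summary_stat,
              x$mean_distance_um[1], tail(x$mean_distance_um, 1), x$auc_um_s))
  invisible(x)
}

#' @export
plot.chemotaxis_event <- function(x, ...) {
  graphics::plot(x$times_s, x$mean_distance_um, type = "b",
                 xlab = "time (s)", ylab = "leading-edge distance (um)",
                 main = paste("chemotaxis event", x$event_id), ...)
  invisible(x)
}

#' Area under the chemotaxis distance-time curve
#'
#' Trapezoidal integral of the per-frame summary distance over time in
#' seconds, across the event's full acquired time-course (no extrapolation).
#' Lower AUC means faster convergence on the lesion. Frames with a missing
#' summary are bridged by linear interpolation; the number of bridged frames
#' is recorded in the `interpolated_frames` attribute.
#'
#' @param event a [response_curve()] result.
#' @return AUC in um*s.
#' @export
chemotaxis_auc <- function(event) {
  y <- event$mean_distance_um
  t <- event$times_s
  ok <- !is.na(y)
  if (sum(ok) < 2) stop("AUC needs at least 2 frames with a defined distance")
  n_interp <- sum(!ok)
  if (n_interp > 0) {
    y <- approx(t[ok], y[ok], xout = t, rule = 2)$y
  }
  auc <- sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)
  attr(auc, "interpolated_frames") <- n_interp
  auc
}

#' Aggregate chemotaxis events per animal
#'
#' Each chemotactic event is one biological unit (the coordinated response of
#' all microglia involved); event AUCs are averaged per animal so that every
#' animal contributes a single value to the group comparison.
#'
#' @param events list of `chemotaxis_event` objects, or a `data.frame` with
#'   columns `animal_id`, `genotype_group`, `auc_um_s`.
#' @return `data.frame` with one row per animal: group, mean AUC, event
#'   count. Empty input yields an empty table with a warning.
#' @export
aggregate_events <- function(events) {
  if (!is.data.frame(events)) {
    if (length(events) == 0) {
      warning("no events to aggregate")
      return(data.frame(animal_id = character(), genotype_group = character(),
                        mean_auc_um_s = numeric(), n_events = integer()))
    }
    events <- do.call(rbind, lapply(events, function(e) {
      if (is.na(e$animal_id)) stop("event ", e$event_id, " missing animal_id")
      data.frame(animal_id = e$animal_id, genotype_group = e$genotype_group,
                 auc_um_s = as.numeric(e$auc_um_s))
    }))
  }
  if (nrow(events) == 0) {
    warning("no events to aggregate")
    return(data.frame(animal_id = character(), genotype_group = character(),
                      mean_auc_um_s = numeric(), n_events = integer()))
  }
  if (anyNA(events$animal_id)) stop("event missing animal_id")
  agg <- aggregate(auc_um_s ~ animal_id + genotype_group, events, mean)
  cnt <- aggregate(auc_um_s ~ animal_id + genotype_group, events, length)
  names(agg)[3] <- "mean_auc_um_s"
  agg$n_events <- cnt$auc_um_s[match(agg$animal_id, cnt$animal_id)]
  agg[order(agg$genotype_group, agg$animal_id), , drop = FALSE]
}
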