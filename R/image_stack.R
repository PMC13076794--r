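#' Calibrated image stack
#'
#' Container for a fluorescence time-lapse (or single-timepoint) stack with
#' physical calibration. Data are stored as a 4D array with dimensions
#' `T x Z x Y x X`; single-plane data keep a degenerate Z (extent 1).
#' The default calibration mirrors a typical two-photon acquisition:
#' 512 x 512 pixels over a 258 um square field (0.504 um/px), 2 um z-steps,
#' one frame per minute.
#'
#' @param data numeric array. Accepted shapes: `T x Z x Y x X`, `T x Y x X`
#'   (Z = 1 inserted), or `Y x X` (single frame, single plane).
#' @param pixel_size_um lateral pixel size in micrometers (> 0).
#' @param z_step_um axial step in micrometers (> 0).
#' @param frame_interval_s time between frames in seconds (> 0).
#' @param channel_label free-text channel description.
#' @param provenance list of processing records; managed by the preprocessing
#'   functions, each of which appends exactly one record.
#' @return An object of class `image_stack`.
#' @examples
#' st <- image_stack(array(runif(2 * 1 * 8 * 8), c(2, 1, 8, 8)),
#'                   pixel_size_um = 0.5, frame_interval_s = 60)
#' dim(st$data)
#' @export
image_stack <- function(data, pixel_size_um, z_step_um = 2,
                        frame_interval_s = 60, channel_label = "GFP",
                        provenance = list()) {
  if (is.matrix(data)) dim(data) <- c(1L, 1L, nrow(data), ncol(data))
  if (length(dim(data)) == 3L)
    dim(data) <- c(dim(data)[1L], 1L, dim(data)[2L], dim(data)[3L])
  if (length(dim(data)) != 4L)
    stop("`data` must have 2, 3 (T,Y,X) or 4 (T,Z,Y,X) dimensions")
  if (!all(is.finite(data)) || any(data < 0))
    stop("intensities must be finite and >= 0")
  for (nm in c("pixel_size_um", "z_step_um", "frame_interval_s")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("`", nm, "` must be a single positive number")
  }
  structure(list(data = data, pixel_size_um = pixel_size_um,
                 z_step_um = z_step_um, frame_interval_s = frame_interval_s,
                 channel_label = channel_label, provenance = provenance),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> T=%d Z=%d Y=%d X=%d\n", d[1], d[2], d[3], d[4]))
  cat(sprintf("  pixel %g um, z-step %g um, frame interval %g s (%s)\n",
              x$pixel_size_um, x$z_step_um, x$frame_interval_s, x$channel_label))
  if (length(x$provenance))
    cat("  provenance:", paste(vapply(x$provenance, `[[`, "", "step"),
                               collapse = " -> "), "\n")
  invisible(x)
}

n_frames <- function(stack) dim(stack$data)[1L]

frame_array <- function(stack, t) {
  # Z x Y x X array of one frame
  a <- stack$data[t, , , , drop = FALSE]
  dim(a) <- dim(stack$data)[2:4]
  a
}

add_provenance <- function(stack, step, params) {
  stack$provenance <- c(stack$provenance, list(list(step = step, params = params)))
  stack
}

#' Read a stack from TIFF with a JSON calibration sidecar
#'
#' Reads a multi-page TIFF written by [write_stack()] (pages in T-major,
#' Z-minor order) or any plain TIFF. Calibration and axis layout are taken
#' from a JSON sidecar (`<path>.json`, written alongside by this package),
#' and can be overridden by the explicit arguments. A plain TIFF without a
#' sidecar requires `pixel_size_um`, `frame_interval_s` and the axis layout
#' (`n_z`) to be given; otherwise an error is raised.
#'
#' @param path TIFF file path.
#' @param pixel_size_um,z_step_um,frame_interval_s calibration overrides.
#' @param n_z number of z-slices per time point (axis override); pages are
#'   interpreted as T blocks of Z pages each.
#' @param channel_label optional channel override.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, pixel_size_um = NULL, z_step_um = NULL,
                       frame_interval_s = NULL, n_z = NULL,
                       channel_label = NULL) {
  if (!file.exists(path)) stop("cannot read stack: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pick <- function(override, key) {
    if (!is.null(override)) return(override)
    if (!is.null(meta[[key]])) return(meta[[key]])
    NULL
  }
  px <- pick(pixel_size_um, "pixel_size_um")
  zs <- pick(z_step_um, "z_step_um")
  fi <- pick(frame_interval_s, "frame_interval_s")
  nz <- pick(n_z, "n_z")
  ch <- pick(channel_label, "channel_label")
  if (is.null(px) || is.null(fi))
    stop("calibration missing: no sidecar metadata and no override for ",
         "pixel_size_um/frame_interval_s")
  if (is.null(zs)) zs <- 2
  if (is.null(nz)) nz <- 1L
  if (is.null(ch)) ch <- "unknown"
  nz <- as.integer(nz)
  np <- length(pages)
  if (np %% nz != 0L) stop("page count ", np, " not divisible by n_z = ", nz)
  nt <- np %/% nz
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  data <- array(0, c(nt, nz, ny, nx))
  for (t in seq_len(nt))
    for (z in seq_len(nz))
      data[t, z, , ] <- pages[[(t - 1L) * nz + z]]
  scale <- meta[["intensity_scale"]]
  if (!is.null(scale)) data <- data * scale
  image_stack(data, pixel_size_um = px, z_step_um = zs,
              frame_interval_s = fi, channel_label = ch)
}

#' Write a stack to multi-page TIFF plus JSON sidecar
#'
#' Pages are written in T-major, Z-minor order (all z-slices of frame 1, then
#' frame 2, ...). Intensities are stored as 16-bit; the linear scale factor
#' needed to recover the original values is recorded in the sidecar, which
#' also carries the axis layout and physical calibration read back by
#' [read_stack()].
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path; `<path>.json` is written alongside.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$data)
  mx <- max(stack$data)
  scale <- if (mx > 0) mx else 1
  pages <- vector("list", d[1] * d[2])
  for (t in seq_len(d[1]))
    for (z in seq_len(d[2]))
      pages[[(t - 1L) * d[2] + z]] <- stack$data[t, z, , ] / scale
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(axes = "TZYX", n_t = d[1], n_z = d[2], n_y = d[3], n_x = d[4],
               pixel_size_um = stack$pixel_size_um, z_step_um = stack$z_step_um,
               frame_interval_s = stack$frame_interval_s,
               channel_label = stack$channel_label,
               intensity_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
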