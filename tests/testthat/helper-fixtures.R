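# shared fixtures and brute-force oracles, built in code at test time

disc_mask <- function(r, pad = 5) {
  n <- 2 * r + 2 * pad + 1
  cx <- r + pad + 1
  outer(seq_len(n), seq_len(n), function(y, x) (y - cx)^2 + (x - cx)^2 <= r^2)
}

digital_ball <- function(r) {
  g <- as.matrix(expand.grid(z = -r:r, y = -r:r, x = -r:r))
  g[rowSums(g^2) <= r^2, , drop = FALSE]
}

ball_volume <- function(r, pad = 2) {
  n <- 2 * r + 2 * pad + 1
  vol <- array(FALSE, c(n, n, n))
  vol[digital_ball(r) + r + pad + 1] <- TRUE
  vol
}

random_blob_mask <- function(ny, nx, p = 0.4) {
  matrix(runif(ny * nx) < p, ny, nx)
}

# exhaustive PE/PR by per-pixel loop
oracle_pe_pr <- function(a, b) {
  pe <- 0L; pr <- 0L
  for (i in seq_len(nrow(a)))
    for (j in seq_len(ncol(a))) {
      if (b[i, j] && !a[i, j]) pe <- pe + 1L
      if (a[i, j] && !b[i, j]) pr <- pr + 1L
    }
  c(pe, pr)
}

# exhaustive clipped-window median
oracle_median_filter <- function(x, r) {
  ny <- nrow(x); nx <- ncol(x)
  out <- x
  for (i in seq_len(ny))
    for (j in seq_len(nx)) {
      w <- x[max(1, i - r):min(ny, i + r), max(1, j - r):min(nx, j + r)]
      out[i, j] <- median(w)
    }
  out
}

# exhaustive per-pixel angle binning
oracle_sectors <- function(mask, center, n_sectors) {
  out <- matrix(NA_integer_, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask)))
    for (j in seq_len(ncol(mask))) {
      if (!mask[i, j]) next
      th <- atan2(-((i - 1) - center[1]), (j - 1) - center[2]) %% (2 * pi)
      out[i, j] <- as.integer(min(n_sectors - 1L, floor(n_sectors * th / (2 * pi))))
    }
  out
}

# exhaustive per-sector minimum distance
oracle_sector_min <- function(mask, center, n_sectors, px) {
  sec <- oracle_sectors(mask, center, n_sectors)
  out <- rep(NA_real_, n_sectors)
  for (i in seq_len(nrow(mask)))
    for (j in seq_len(ncol(mask))) {
      if (!mask[i, j]) next
      d <- sqrt(((i - 1) - center[1])^2 + ((j - 1) - center[2])^2) * px
      s <- sec[i, j] + 1L
      if (is.na(out[s]) || d < out[s]) out[s] <- d
    }
  out
}

# exhaustive 256-bin Otsu (between-class variance maximization)
oracle_otsu <- function(x, n_bins = 256L) {
  lo <- min(x); hi <- max(x)
  h <- tabulate(pmin(n_bins, floor((x - lo) / (hi - lo) * n_bins) + 1L), n_bins)
  mids <- lo + (seq_len(n_bins) - 0.5) / n_bins * (hi - lo)
  best <- -Inf; bk <- 1L
  for (k in seq_len(n_bins - 1L)) {
    w0 <- sum(h[1:k]); w1 <- sum(h) - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(h[1:k] * mids[1:k]) / w0
    m1 <- sum(h[(k + 1):n_bins] * mids[(k + 1):n_bins]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best) { best <- v; bk <- k }
  }
  lo + bk / n_bins * (hi - lo)
}

# independent marching-squares midpoint polygon length (configuration table)
oracle_contour_length <- function(mask) {
  m <- matrix(0, nrow(mask) + 2, ncol(mask) + 2)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask * 1
  a <- m[-nrow(m), -ncol(m)]; b <- m[-nrow(m), -1]
  cc <- m[-1, -ncol(m)]; d <- m[-1, -1]
  code <- a + 2 * b + 4 * cc + 8 * d
  h <- sqrt(0.5)
  len <- c(0, h, h, 1, h, 1, 2 * h, h, h, 2 * h, 1, h, 1, h, h, 0)
  sum(len[code + 1])
}

# small baseline simulation with clean (noise-free, blur-free) rendering
quick_baseline <- function(seed, ext = 1, ret = 1, n_frames = 6,
                           field_px = 160, field_um = 80, branches = 4L,
                           branch_len = 12, ...) {
  simulate_timelapse(sim_params(
    seed = seed, field_size_px = c(field_px, field_px), field_size_um = field_um,
    n_frames = n_frames, n_primary_branches = branches,
    branch_length_um = branch_len, branch_prob = 0, max_branch_depth = 1L,
    extension_rate_um_per_min = ext, retraction_rate_um_per_min = ret,
    noise_model = "none", psf_sigma_px = 0, ...))
}

masks_from_stack <- function(sim) {
  proj <- max_project(sim$stack)
  make_cell_masks(proj, cell_annotation("cell",
                                        threshold_value = sim$truth$threshold_mid))
}
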