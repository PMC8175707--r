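# Circular-ROI kymographs and treadmilling-velocity estimation.
#
# A circular region (typically r = 0.5 um, the cross-section of an inward
# conical membrane deformation) is sampled along three concentric circles of
# radii r-1, r, r+1 pixels; the per-frame angular intensity profiles are
# averaged into an angle x time kymograph whose linear streaks encode the
# tangential speed and direction of treadmilling filaments.

#' Fit a circle to pixel coordinates
#'
#' Two points are treated as diameter endpoints. Three or more points are fit
#' by algebraic (Kasa) least squares, minimizing squared radial residuals in
#' the linearized form.
#'
#' @param points numeric matrix or data.frame with columns x, y (0-based
#'   pixel coordinates), at least 2 distinct rows
#' @param pixel_size_um optional pixel size to fill the physical radius
#' @return a \code{CircularROI}: list(center_xy, radius_px, radius_um)
#' @export
fit_circle <- function(points, pixel_size_um = NULL) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  pts <- unique(round(pts, 12))
  n <- nrow(pts)
  if (n < 2) stop("need at least 2 distinct points")
  if (n == 2) {
    center <- colMeans(pts)
    radius <- sqrt(sum((pts[1, ] - pts[2, ])^2)) / 2
  } else {
    x <- pts[, 1]; y <- pts[, 2]
    A <- cbind(2 * x, 2 * y, 1)
    if (qr(cbind(x - mean(x), y - mean(y)))$rank < 2) {
      stop("degenerate fit: points are collinear")
    }
    sol <- qr.solve(A, x^2 + y^2)
    center <- sol[1:2]
    radius <- sqrt(sol[3] + sum(center^2))
  }
  if (radius < 2) warning("fitted radius below 2 px; kymograph undersampled")
  structure(list(center_xy = unname(center), radius_px = unname(radius),
                 radius_um = if (is.null(pixel_size_um)) NA_real_ else
                   radius * pixel_size_um),
            class = "CircularROI")
}

#' Compute an angle x time kymograph over a circular ROI
#'
#' For each frame, intensity is sampled by bilinear interpolation along the
#' three concentric circles of radii r-1, r, r+1 pixels at a fixed angular
#' grid of one-pixel arc length (n_bins = round(2 pi r)), and the three
#' profiles are averaged with equal weight.
#'
#' @param stack an \code{\link{image_stack}}
#' @param roi a \code{\link{fit_circle}} result (or list with center_xy,
#'   radius_px)
#' @param channel channel name or index to sample
#' @return a \code{Kymograph}: list(matrix [angle_bin, frame],
#'   angle_step_rad, frame_interval_s, arc_length_per_bin_um, radius_um)
#' @export
compute_kymograph <- function(stack, roi, channel = 1) {
  stopifnot(inherits(stack, "ImageStack"))
  r <- roi$radius_px
  if (r - 1 < 1) stop("inner circle radius below 1 px")
  d <- dim(stack$pixels)
  cx <- roi$center_xy[1]; cy <- roi$center_xy[2]
  if (cx - (r + 1) < 0 || cx + (r + 1) > d[2] - 1 ||
      cy - (r + 1) < 0 || cy + (r + 1) > d[1] - 1) {
    stop(sprintf("circle of radius %.1f px at (%.1f, %.1f) exits image (all frames)",
                 r + 1, cx, cy))
  }
  n_bins <- max(8L, round(2 * pi * r))
  theta <- (seq_len(n_bins) - 1) * 2 * pi / n_bins
  if (is.character(channel)) channel <- match(channel, stack$channels)
  mat <- matrix(0, n_bins, d[4])
  for (f in seq_len(d[4])) {
    img <- stack$pixels[, , channel, f]
    prof <- rep(0, n_bins)
    for (rr in c(r - 1, r, r + 1)) {
      prof <- prof + bilinear_sample(img, cx + rr * cos(theta),
                                     cy + rr * sin(theta))
    }
    mat[, f] <- prof / 3
  }
  radius_um <- if (!is.null(roi$radius_um) && is.finite(roi$radius_um)) {
    roi$radius_um
  } else r * stack$pixel_size_um
  structure(list(matrix = mat, angle_step_rad = 2 * pi / n_bins,
                 frame_interval_s = stack$frame_interval_s,
                 arc_length_per_bin_um = radius_um * 2 * pi / n_bins,
                 radius_um = radius_um),
            class = "Kymograph")
}

#' Estimate tangential treadmilling velocities from a kymograph
#'
#' Ridge points (per-frame angular intensity maxima above median + 3 MAD of
#' the kymograph) are linked into tracks by nearest-angle association with
#' circular unwrapping; each track of at least \code{min_track} frames is fit
#' by linear regression of unwrapped angle on time. Positive slope (angle
#' increasing, y-down coordinates) is reported as anticlockwise.
#'
#' @param kymo a \code{\link{compute_kymograph}} result
#' @param min_track minimum track length in frames
#' @param max_jump_bins maximum per-frame angular jump for linking (default
#'   1/8 turn)
#' @return data.frame with one row per detected streak: speed_um_per_s,
#'   direction ("clockwise"/"anticlockwise"/NA), slope_px_per_frame,
#'   n_frames. Zero rows when nothing exceeds the threshold.
#' @export
estimate_velocity <- function(kymo, min_track = 5L, max_jump_bins = NULL) {
  stopifnot(inherits(kymo, "Kymograph"))
  m <- kymo$matrix
  n_bins <- nrow(m); n_frames <- ncol(m)
  if (n_frames < 5) stop("need at least 5 frames")
  thr <- stats::median(m) + 3 * stats::mad(m)
  max_jump_bins <- max_jump_bins %||% max(2, n_bins / 8)

  # per-frame ridge points: circular local maxima above threshold
  peaks_by_frame <- lapply(seq_len(n_frames), function(f) {
    v <- m[, f]
    pad <- 5L
    vc <- c(v[(n_bins - pad + 1):n_bins], v, v[1:pad])
    p <- find_peaks(vc, min_prominence = 0.25 * (max(v) - thr),
                    min_separation = 3L) - pad
    p <- p[p >= 1 & p <= n_bins]
    p <- p[v[p] > thr]
    vapply(p, function(i) refine_peak_circular(v, i), numeric(1))
  })

  # greedy nearest-angle linking into tracks (unwrapped bins)
  tracks <- list()
  active <- list()   # each: list(frames, bins_unwrapped, last)
  for (f in seq_len(n_frames)) {
    pts <- peaks_by_frame[[f]]
    used <- rep(FALSE, length(pts))
    for (ti in seq_along(active)) {
      tr <- active[[ti]]
      if (!length(pts)) break
      dists <- circ_diff(pts, tr$last %% n_bins, n_bins)
      j <- which.min(abs(dists))
      if (!used[j] && abs(dists[j]) <= max_jump_bins &&
          f - tr$frames[length(tr$frames)] <= 2) {
        tr$bins <- c(tr$bins, tr$last + dists[j])
        tr$last <- tr$last + dists[j]
        tr$frames <- c(tr$frames, f)
        active[[ti]] <- tr
        used[j] <- TRUE
      }
    }
    for (j in which(!used)) {
      active[[length(active) + 1]] <- list(frames = f, bins = pts[j],
                                           last = pts[j])
    }
    # retire stale tracks
    stale <- vapply(active, function(tr) f - tr$frames[length(tr$frames)] > 2,
                    logical(1))
    tracks <- c(tracks, active[stale])
    active <- active[!stale]
  }
  tracks <- c(tracks, active)
  tracks <- Filter(function(tr) length(tr$frames) >= min_track, tracks)

  if (!length(tracks)) {
    return(data.frame(speed_um_per_s = numeric(0), direction = character(0),
                      slope_px_per_frame = numeric(0), n_frames = integer(0)))
  }
  res <- do.call(rbind, lapply(tracks, function(tr) {
    fit <- stats::lm(tr$bins ~ tr$frames)
    slope <- unname(stats::coef(fit)[2])      # bins per frame
    speed <- abs(slope) * kymo$arc_length_per_bin_um / kymo$frame_interval_s
    # direction resolvable only when total drift exceeds one bin
    total_drift <- abs(slope) * diff(range(tr$frames))
    dir <- if (total_drift < 1) NA_character_ else {
      if (slope > 0) "anticlockwise" else "clockwise"
    }
    data.frame(speed_um_per_s = speed, direction = dir,
               slope_px_per_frame = slope, n_frames = length(tr$frames))
  }))
  res[order(-res$n_frames), , drop = FALSE]
}

# signed circular bin difference in (-n/2, n/2]
circ_diff <- function(a, b, n) {
  d <- (a - b) %% n
  ifelse(d > n / 2, d - n, d)
}

refine_peak_circular <- function(v, i) {
  n <- length(v)
  im <- if (i == 1) n else i - 1
  ip <- if (i == n) 1 else i + 1
  denom <- v[im] - 2 * v[i] + v[ip]
  if (denom >= 0) return(as.numeric(i))
  i + 0.5 * (v[im] - v[ip]) / denom
}
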