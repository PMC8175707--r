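# Single-ring photometry: integrated brightness of protein rings on a
# surface, rim-to-rim ring diameter from intensity profiles, and
# brightness-based counting of ring units on a tube.

#' Background-subtracted integrated brightness of one ring
#'
#' Sums intensity in a square box around the ring centre and subtracts the
#' median of a surrounding annulus times the box area. SNR is the integrated
#' signal over the annulus noise propagated across the box.
#'
#' @param image numeric matrix
#' @param center_xy ring centre, 0-based (x, y)
#' @param box_halfwidth_px half-width of the measurement box, px
#' @param annulus_px width of the background annulus around the box, px
#' @return a \code{RingMeasurement}: list(center_xy, integrated_brightness,
#'   background_per_px, snr)
#' @export
ring_brightness <- function(image, center_xy, box_halfwidth_px = 8L,
                            annulus_px = 3L) {
  nr <- nrow(image); nc <- ncol(image)
  cx <- round(center_xy[1]) + 1L; cy <- round(center_xy[2]) + 1L
  h <- box_halfwidth_px; a <- annulus_px
  if (cx - h - a < 1 || cx + h + a > nc || cy - h - a < 1 || cy + h + a > nr) {
    stop("measurement box plus background annulus exits the image")
  }
  box <- image[(cy - h):(cy + h), (cx - h):(cx + h)]
  outer_box <- image[(cy - h - a):(cy + h + a), (cx - h - a):(cx + h + a)]
  # annulus = outer box minus inner box
  inner_mask <- matrix(FALSE, 2 * (h + a) + 1, 2 * (h + a) + 1)
  inner_mask[(a + 1):(a + 2 * h + 1), (a + 1):(a + 2 * h + 1)] <- TRUE
  ann <- outer_box[!inner_mask]
  bg <- stats::median(ann)
  integrated <- sum(box) - bg * length(box)
  noise <- stats::sd(ann) * sqrt(length(box))
  structure(list(center_xy = center_xy, integrated_brightness = integrated,
                 background_per_px = bg,
                 snr = if (noise > 0) integrated / noise else Inf),
            class = "RingMeasurement")
}

#' Measure all rings in an image against a detection table
#'
#' Detections whose boxes overlap are flagged and excluded from reference
#' statistics (clumped rings bias the single-ring brightness reference).
#'
#' @param image numeric matrix
#' @param detections data.frame with x_px, y_px (0-based centres)
#' @inheritParams ring_brightness
#' @return data.frame: x_px, y_px, integrated_brightness, snr, overlapping
#' @export
measure_ring_field <- function(image, detections, box_halfwidth_px = 8L,
                               annulus_px = 3L) {
  n <- nrow(detections)
  overlap <- rep(FALSE, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (max(abs(detections$x_px[i] - detections$x_px[j]),
              abs(detections$y_px[i] - detections$y_px[j])) <=
          2 * box_halfwidth_px) {
        overlap[i] <- overlap[j] <- TRUE
      }
    }
  }
  res <- lapply(seq_len(n), function(i) {
    m <- tryCatch(
      ring_brightness(image, c(detections$x_px[i], detections$y_px[i]),
                      box_halfwidth_px, annulus_px),
      error = function(e) list(integrated_brightness = NA_real_,
                               snr = NA_real_))
    data.frame(x_px = detections$x_px[i], y_px = detections$y_px[i],
               integrated_brightness = m$integrated_brightness, snr = m$snr)
  })
  out <- do.call(rbind, res)
  # rings too close to the border (box exits the image) are excluded like
  # overlapping ones
  out$overlapping <- overlap | is.na(out$integrated_brightness)
  out
}

#' Reference per-ring brightness from a set of single-ring measurements
#'
#' The reference statistic is the median of accepted (non-overlapping,
#' positive-brightness) rings; robust to residual clumps. A reference built
#' from fewer than 10 rings is flagged.
#'
#' @param measurements data.frame from \code{\link{measure_ring_field}}
#' @return list(per_ring_brightness, n_used, reliable)
#' @export
ring_brightness_reference <- function(measurements) {
  ok <- !measurements$overlapping &
    !is.na(measurements$integrated_brightness) &
    measurements$integrated_brightness > 0
  n <- sum(ok)
  if (n == 0) stop("no accepted rings for the brightness reference")
  list(per_ring_brightness =
         stats::median(measurements$integrated_brightness[ok]),
       n_used = n, reliable = n >= 10)
}

#' Ring diameter from an intensity profile through the centre
#'
#' The diameter is the distance between the two rim peaks, refined to
#' sub-pixel positions by parabolic interpolation.
#'
#' @param intensity profile values
#' @param spacing_um sample spacing, um
#' @param min_prominence_frac rim-peak prominence threshold (fraction of
#'   profile range)
#' @return list(diameter_um, peak_positions_um, resolved)
#' @export
ring_diameter <- function(intensity, spacing_um,
                          min_prominence_frac = 0.15) {
  v <- as.numeric(intensity)
  p <- find_peaks(v, min_prominence = min_prominence_frac * diff(range(v)),
                  min_separation = 2L)
  if (length(p) < 2) {
    return(list(diameter_um = NA_real_, peak_positions_um = numeric(0),
                resolved = FALSE))
  }
  # the two strongest peaks are the rims
  p <- p[order(-v[p])][1:2]
  pos <- sort(vapply(p, function(i) refine_peak(v, i), numeric(1)))
  list(diameter_um = diff(pos) * spacing_um,
       peak_positions_um = (pos - 1) * spacing_um, resolved = TRUE)
}

#' Count ring units on a tube from its total protein brightness
#'
#' n_rings = tube brightness / per-ring reference brightness;
#' rings_per_um = n_rings / tube length.
#'
#' @param tube_protein_brightness background-subtracted integrated protein
#'   brightness of the tube
#' @param per_ring_brightness_ref reference brightness of one ring
#' @param tube_length_um tube length, um
#' @param n_reference_rings number of rings behind the reference (a value
#'   below 10 flags the result)
#' @return a \code{RingCount}: list(n_rings, rings_per_um,
#'   per_ring_brightness_ref, reliable)
#' @export
count_rings_on_tube <- function(tube_protein_brightness,
                                per_ring_brightness_ref, tube_length_um,
                                n_reference_rings = NA_integer_) {
  stopifnot(per_ring_brightness_ref > 0, tube_length_um > 0)
  n_rings <- tube_protein_brightness / per_ring_brightness_ref
  structure(list(n_rings = n_rings,
                 rings_per_um = n_rings / tube_length_um,
                 per_ring_brightness_ref = per_ring_brightness_ref,
                 reliable = is.na(n_reference_rings) ||
                   n_reference_rings >= 10),
            class = "RingCount")
}

#' Detect ring candidates by difference-of-Gaussians blob response
#'
#' Batch-mode stand-in for visual ring picking: a DoG bandpass tuned to the
#' expected ring radius, local 2-d maxima above a MAD-based threshold.
#'
#' @param image numeric matrix
#' @param expected_radius_px expected ring radius, px
#' @param threshold_mads detection threshold in MADs above the median
#'   response
#' @return data.frame(x_px, y_px) of candidate centres (0-based)
#' @export
detect_rings <- function(image, expected_radius_px, threshold_mads = 5) {
  s1 <- max(1, expected_radius_px / sqrt(2))
  dog <- gaussian_blur(image, s1) - gaussian_blur(image, 1.6 * s1)
  thr <- stats::median(dog) + threshold_mads * stats::mad(dog)
  nr <- nrow(dog); nc <- ncol(dog)
  cand <- which(dog > thr, arr.ind = TRUE)
  cand <- cand[cand[, 1] > 1 & cand[, 1] < nr &
               cand[, 2] > 1 & cand[, 2] < nc, , drop = FALSE]
  is_max <- vapply(seq_len(nrow(cand)), function(i) {
    r <- cand[i, 1]; cc <- cand[i, 2]
    dog[r, cc] >= max(dog[(r - 1):(r + 1), (cc - 1):(cc + 1)])
  }, logical(1))
  cand <- cand[is_max, , drop = FALSE]
  # merge maxima closer than one radius
  keep <- rep(TRUE, nrow(cand))
  if (nrow(cand) > 1) {
    ord <- order(-dog[cand])
    cand <- cand[ord, , drop = FALSE]
    for (i in 2:nrow(cand)) {
      d <- sqrt((cand[1:(i - 1), 1] - cand[i, 1])^2 +
                (cand[1:(i - 1), 2] - cand[i, 2])^2)
      if (any(d[keep[1:(i - 1)]] < expected_radius_px)) keep[i] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  data.frame(x_px = cand[, 2] - 1, y_px = cand[, 1] - 1)
}
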