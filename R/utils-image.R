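# Small image-processing primitives (no image package in the dependency
# stack provides these): bilinear sampling, separable Gaussian blur, Otsu
# threshold, connected components, 1-d peak finding.

#' Bilinearly sample an image at (possibly fractional) pixel coordinates
#'
#' Coordinate convention: row-major matrix, origin top-left, x = column,
#' y = row, 0-based (pixel centres at integer coordinates). Points must lie
#' inside the image bounds.
#'
#' @param img numeric matrix
#' @param x,y numeric vectors of 0-based column/row coordinates
#' @return numeric vector of interpolated intensities
#' @export
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  if (any(x < 0 | x > nc - 1 | y < 0 | y > nr - 1)) {
    stop("bilinear_sample: coordinates outside image bounds")
  }
  x0 <- pmin(floor(x), nc - 2); y0 <- pmin(floor(y), nr - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- img[cbind(y0 + 1, x0 + 1)]
  i01 <- img[cbind(y0 + 1, x0 + 2)]
  i10 <- img[cbind(y0 + 2, x0 + 1)]
  i11 <- img[cbind(y0 + 2, x0 + 2)]
  i00 * (1 - fx) * (1 - fy) + i01 * fx * (1 - fy) +
    i10 * (1 - fx) * fy + i11 * fx * fy
}

#' Separable Gaussian blur
#'
#' @param img numeric matrix
#' @param sigma_px kernel standard deviation in pixels; 0 returns the input
#' @return blurred matrix of the same dimensions (replicated-edge padding)
#' @export
gaussian_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  half <- max(1L, ceiling(3 * sigma_px))
  k <- dnorm(seq(-half, half), sd = sigma_px)
  k <- k / sum(k)
  img <- apply(img, 2, convolve_replicate, k = k)
  t(apply(t(img), 2, convolve_replicate, k = k))
}

convolve_replicate <- function(v, k) {
  half <- (length(k) - 1L) / 2L
  padded <- c(rep(v[1], half), v, rep(v[length(v)], half))
  as.numeric(stats::filter(padded, k, sides = 2))[(half + 1L):(half + length(v))]
}

#' Otsu's threshold for a grey-level image
#'
#' Maximizes between-class variance on a 256-bin histogram of the intensity
#' range. Returns a threshold in intensity units; pixels strictly above it
#' are foreground.
#'
#' @param img numeric matrix or vector
#' @param n_bins histogram resolution
#' @return scalar threshold
#' @export
otsu_threshold <- function(img, n_bins = 256L) {
  v <- as.numeric(img)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(n_bins, 1L + floor((v - rng[1]) / diff(rng) * n_bins)),
                nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  mids[which.max(sigma_b)]
}

#' Label 4-connected components of a logical mask
#'
#' Iterative minimum-label propagation; adequate for the small masks handled
#' here. Returns an integer matrix with 0 for background and 1..k for
#' components (labels are made contiguous, largest component first).
#'
#' @param mask logical matrix
#' @return integer label matrix
#' @export
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  repeat {
    nb <- lab
    # shift up / down / left / right, take elementwise minimum over foreground
    up    <- rbind(lab[-1, , drop = FALSE], rep(Inf, nc))
    down  <- rbind(rep(Inf, nc), lab[-nr, , drop = FALSE])
    left  <- cbind(lab[, -1, drop = FALSE], rep(Inf, nr))
    right <- cbind(rep(Inf, nr), lab[, -nc, drop = FALSE])
    for (s in list(up, down, left, right)) {
      s[s == 0] <- Inf
      nb <- pmin(nb, matrix(s, nr, nc))
    }
    nb[!mask] <- 0
    nb[is.infinite(nb)] <- lab[is.infinite(nb)]
    if (identical(nb, lab)) break
    lab <- nb
  }
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids)) {
    sizes <- vapply(ids, function(i) sum(lab == i), numeric(1))
    ord <- ids[order(-sizes)]
    relab <- integer(max(ids))
    relab[ord] <- seq_along(ord)
    lab[lab > 0] <- relab[lab[lab > 0]]
  }
  storage.mode(lab) <- "integer"
  lab
}

#' Find local maxima of a 1-d trace with prominence and separation rules
#'
#' A point is a peak if it is a strict local maximum, its prominence (height
#' above the higher of the two flanking minima down to the lower neighbouring
#' peak base) exceeds \code{min_prominence}, and peaks closer than
#' \code{min_separation} are pruned keeping the higher one.
#'
#' @param v numeric vector
#' @param min_prominence minimum prominence in intensity units
#' @param min_separation minimum index separation between kept peaks
#' @return integer vector of peak indices (1-based), increasing
#' @export
find_peaks <- function(v, min_prominence = 0.1 * diff(range(v)),
                       min_separation = 3L) {
  n <- length(v)
  if (n < 3) return(integer(0))
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    left <- if (any(v[1:(i - 1)] > v[i])) {
      j <- max(which(v[1:(i - 1)] > v[i])); min(v[j:i])
    } else min(v[1:i])
    right <- if (any(v[(i + 1):n] > v[i])) {
      j <- i + min(which(v[(i + 1):n] > v[i])); min(v[i:j])
    } else min(v[i:n])
    v[i] - max(left, right)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  if (length(keep) > 1) {
    ord <- keep[order(-v[keep])]
    sel <- logical(0)
    chosen <- integer(0)
    for (i in ord) {
      if (!length(chosen) || all(abs(chosen - i) >= min_separation)) {
        chosen <- c(chosen, i)
      }
    }
    keep <- sort(chosen)
  }
  keep
}

#' Sub-pixel refinement of a peak position by parabolic interpolation
#'
#' @param v numeric vector
#' @param i integer index of a local maximum of v
#' @return refined (fractional) index
#' @export
refine_peak <- function(v, i) {
  if (i <= 1 || i >= length(v)) return(as.numeric(i))
  denom <- v[i - 1] - 2 * v[i] + v[i + 1]
  if (denom >= 0) return(as.numeric(i))
  i + 0.5 * (v[i - 1] - v[i + 1]) / denom
}
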