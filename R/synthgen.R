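# Synthetic-data generators: helical lipid tubes, treadmilling vortices,
# driven-bead detector traces, and fields of protein rings -- each with
# stored ground truth so every downstream estimator can be validated.

#' Configuration for synthetic helical tube stacks
#'
#' Describes a membrane tube pulled from a vesicle and deformed into a helix
#' by membrane-bound filaments: the projected image is a sinusoidal
#' centerline of amplitude \code{helix_radius_um} and axial period
#' \code{pitch_um}, rendered with a Gaussian tube cross-section (FWHM =
#' \code{tube_diameter_um}) blurred by the PSF and sampled with Poisson shot
#' noise.
#'
#' @param pitch_um helical pitch (axial distance per turn), um
#' @param helix_radius_um helix radius (projected amplitude), um
#' @param tube_diameter_um tube diameter = FWHM of the cross-section, um
#' @param tube_length_um axial tube length, um
#' @param protein_coverage fraction of lipid signal mirrored in the protein
#'   channel at the final frame, in [0, 1]
#' @param protein_coverage_initial coverage at the first frame (coverage ramps
#'   linearly across frames; default equal to \code{protein_coverage})
#' @param psf_sigma_um point-spread-function sigma, um
#' @param photons_per_pixel expected photons per axial pixel column (sets the
#'   shot-noise level)
#' @param background_photons expected background photons per pixel
#' @param pixel_size_um physical pixel size, um
#' @param frames number of frames
#' @param noise apply Poisson noise (TRUE) or return the noiseless render
#' @param seed RNG seed; a fixed seed gives bit-identical output
#' @return a \code{SynthTubeConfig} list
#' @export
synth_tube_config <- function(pitch_um = 1.6, helix_radius_um = 0.4,
                              tube_diameter_um = 0.47, tube_length_um = 10,
                              protein_coverage = 0.8,
                              protein_coverage_initial = protein_coverage,
                              psf_sigma_um = 0.25, photons_per_pixel = 1000,
                              background_photons = 2, pixel_size_um = 0.11,
                              frames = 1, noise = TRUE, seed = 1L) {
  cfg <- list(pitch_um = pitch_um, helix_radius_um = helix_radius_um,
              tube_diameter_um = tube_diameter_um,
              tube_length_um = tube_length_um,
              protein_coverage = protein_coverage,
              protein_coverage_initial = protein_coverage_initial,
              psf_sigma_um = psf_sigma_um,
              photons_per_pixel = photons_per_pixel,
              background_photons = background_photons,
              pixel_size_um = pixel_size_um, frames = as.integer(frames),
              noise = isTRUE(noise), seed = as.integer(seed))
  with(cfg, {
    stopifnot(pitch_um > 0, helix_radius_um > 0, tube_diameter_um > 0,
              tube_length_um > 0, psf_sigma_um > 0, pixel_size_um > 0,
              photons_per_pixel > 0, frames >= 1,
              protein_coverage >= 0, protein_coverage <= 1,
              protein_coverage_initial >= 0, protein_coverage_initial <= 1)
  })
  class(cfg) <- "SynthTubeConfig"
  cfg
}

#' Render a two-channel helical tube stack with known ground truth
#'
#' The lipid channel renders a tube whose projected centerline is
#' y(x) = R sin(2 pi x / lambda). Photon deposition is uniform per unit of
#' 3-d helix arclength, so the projection is naturally brighter at the
#' turning points, as in real images of helical tubes. The protein channel
#' is the lipid render scaled by the coverage fraction. Ground truth (pitch,
#' diameter, projected and 3-d arclengths, centerline) is stored in
#' \code{$truth}.
#'
#' @param config a \code{\link{synth_tube_config}}
#' @return an \code{\link{image_stack}} with channels "protein", "lipid"
#' @export
gen_helical_tube_stack <- function(config) {
  stopifnot(inherits(config, "SynthTubeConfig"))
  c0 <- config
  if (c0$pitch_um < 2 * c0$pixel_size_um) {
    stop("pitch below the Nyquist limit of the pixel grid (pitch < 2 px)")
  }
  px <- c0$pixel_size_um
  sigma_tube_um <- c0$tube_diameter_um / (2 * sqrt(2 * log(2)))
  sigma_um <- sqrt(sigma_tube_um^2 + c0$psf_sigma_um^2)
  margin_um <- 4 * sigma_um + 2 * px
  nr <- ceiling((2 * c0$helix_radius_um + 2 * margin_um) / px)
  nc <- ceiling((c0$tube_length_um + 2 * margin_um) / px)
  y_c <- (nr - 1) / 2                      # tube axis row (0-based)
  x0 <- margin_um / px                     # axial start column (0-based)

  # centerline sampled uniformly in helix phase; uniform 3-d arclength deposit
  n_turns <- c0$tube_length_um / c0$pitch_um
  ds3_per_dtheta <- sqrt((c0$pitch_um / (2 * pi))^2 + c0$helix_radius_um^2)
  n_pts <- max(200L, ceiling(n_turns * 2 * pi * ds3_per_dtheta / (px / 4)))
  theta <- seq(0, n_turns * 2 * pi, length.out = n_pts)
  cx <- x0 + (theta / (2 * pi)) * c0$pitch_um / px
  cy <- y_c + (c0$helix_radius_um / px) * sin(theta)

  base <- deposit_gaussians(nr, nc, cx, cy, sigma_um / px,
                            weights = rep(1, n_pts))
  total_photons <- c0$photons_per_pixel * c0$tube_length_um / px
  base <- base * (total_photons / sum(base))

  # ground truth arclengths: 3-d helix (constant integrand) and 2-d projection
  arclength_3d <- c0$tube_length_um *
    sqrt(1 + (2 * pi * c0$helix_radius_um / c0$pitch_um)^2)
  dydx <- function(x) (2 * pi * c0$helix_radius_um / c0$pitch_um) *
    cos(2 * pi * x / c0$pitch_um)
  arclength_2d <- stats::integrate(function(x) sqrt(1 + dydx(x)^2), 0,
                                   c0$tube_length_um,
                                   subdivisions = 2000L)$value

  px_arr <- array(0, dim = c(nr, nc, 2, c0$frames))
  cov <- if (c0$frames == 1) c0$protein_coverage else {
    seq(c0$protein_coverage_initial, c0$protein_coverage,
        length.out = c0$frames)
  }
  set.seed(c0$seed)
  for (f in seq_len(c0$frames)) {
    lipid <- base + c0$background_photons
    protein <- cov[f] * base + c0$background_photons
    if (c0$protein_coverage == 0 && c0$protein_coverage_initial == 0) {
      protein <- matrix(c0$background_photons, nr, nc)
    }
    if (c0$noise) {
      lipid <- matrix(stats::rpois(nr * nc, lipid), nr, nc)
      protein <- matrix(stats::rpois(nr * nc, protein), nr, nc)
    }
    px_arr[, , 1, f] <- protein
    px_arr[, , 2, f] <- lipid
  }
  image_stack(px_arr, px, channels = c("protein", "lipid"),
              truth = list(pitch_um = c0$pitch_um,
                           helix_radius_um = c0$helix_radius_um,
                           tube_diameter_um = c0$tube_diameter_um,
                           # FWHM a profile fit on the image should see:
                           # tube cross-section convolved with the PSF
                           diameter_observed_um = 2 * sqrt(2 * log(2)) *
                             sigma_um,
                           tube_length_um = c0$tube_length_um,
                           arclength_2d_um = arclength_2d,
                           arclength_3d_um = arclength_3d,
                           axis_row = y_c, axis_col0 = x0,
                           coverage = cov, config = unclass(c0)))
}

# Accumulate unit-sum Gaussian kernels at fractional centres (cx, cy),
# 0-based pixel coordinates. Each kernel is discretely normalized so total
# deposited intensity equals sum(weights) for kernels inside the frame.
deposit_gaussians <- function(nr, nc, cx, cy, sigma_px, weights) {
  img <- matrix(0, nr, nc)
  half <- ceiling(4 * sigma_px)
  for (i in seq_along(cx)) {
    xi <- round(cx[i]); yi <- round(cy[i])
    xs <- max(0, xi - half):min(nc - 1, xi + half)
    ys <- max(0, yi - half):min(nr - 1, yi + half)
    kx <- exp(-(xs - cx[i])^2 / (2 * sigma_px^2))
    ky <- exp(-(ys - cy[i])^2 / (2 * sigma_px^2))
    k <- outer(ky, kx)
    img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + weights[i] * k / sum(k)
  }
  img
}

#' Render a movie of Gaussian spots rotating on a circle (vortex analogue)
#'
#' Emulates filaments treadmilling around the inner surface of a conical
#' support: one spot per entry of \code{angular_speed_rad_s} rotates on a
#' circle of radius \code{ring_radius_um}; the sign of the angular speed sets
#' the direction (positive = anticlockwise in y-down image coordinates).
#'
#' @param angular_speed_rad_s vector of angular speeds, rad/s (signed)
#' @param ring_radius_um circle radius, um
#' @param initial_angle_rad starting angles (recycled)
#' @param pixel_size_um pixel size, um
#' @param frames number of frames
#' @param frame_interval_s frame interval, s
#' @param psf_sigma_um spot sigma, um
#' @param photons_per_spot expected photons per spot per frame
#' @param background_photons background level
#' @param noise apply Poisson noise
#' @param seed RNG seed
#' @return an \code{\link{image_stack}} (single "protein" channel); truth
#'   stores per-spot tangential speeds |omega| r
#' @export
gen_vortex_movie <- function(angular_speed_rad_s, ring_radius_um,
                             initial_angle_rad = 0, pixel_size_um = 0.11,
                             frames = 60L, frame_interval_s = 1,
                             psf_sigma_um = 0.17, photons_per_spot = 2000,
                             background_photons = 2, noise = TRUE, seed = 1L) {
  r_px <- ring_radius_um / pixel_size_um
  if (r_px < 2) stop("ring radius below 2 pixels is unresolvable")
  n_spots <- length(angular_speed_rad_s)
  initial_angle_rad <- rep_len(initial_angle_rad, n_spots)
  sigma_px <- psf_sigma_um / pixel_size_um
  half <- ceiling(r_px + 4 * sigma_px + 2)
  n <- 2L * half + 1L
  cx0 <- half; cy0 <- half                 # image centre, 0-based
  arr <- array(0, dim = c(n, n, 1, frames))
  set.seed(as.integer(seed))
  for (f in seq_len(frames)) {
    t <- (f - 1) * frame_interval_s
    th <- initial_angle_rad + angular_speed_rad_s * t
    img <- deposit_gaussians(n, n, cx0 + r_px * cos(th), cy0 + r_px * sin(th),
                             sigma_px, rep(photons_per_spot, n_spots))
    img <- img + background_photons
    if (noise) img <- matrix(stats::rpois(n * n, img), n, n)
    arr[, , 1, f] <- img
  }
  image_stack(arr, pixel_size_um, frame_interval_s, channels = "protein",
              truth = list(angular_speed_rad_s = angular_speed_rad_s,
                           tangential_speed_um_s =
                             abs(angular_speed_rad_s) * ring_radius_um,
                           ring_radius_um = ring_radius_um,
                           center_xy = c(cx0, cy0),
                           initial_angle_rad = initial_angle_rad))
}

#' Configuration for synthetic driven-bead QPD traces
#'
#' Forward model of the oscillation-mode force assay: a bead in a harmonic
#' optical trap (stiffness \code{k_trap}) is connected through the
#' tube/filament spring (\code{k_spring_true}) to a stage oscillating as
#' x_p(t) = A sin(2 pi f t). Defaults follow the assay protocol: A = 3 um,
#' f = 1 Hz, 60 s at 10 kHz, bead diameter 1.71 um, k_trap = 74.4 pN/um.
#'
#' @param k_trap_pn_um trap stiffness, pN/um
#' @param k_spring_true_pn_um true tube spring constant, pN/um
#' @param drive_amplitude_um stage oscillation amplitude A, um
#' @param drive_frequency_hz stage oscillation frequency f, Hz
#' @param sampling_rate_hz QPD acquisition rate, Hz
#' @param duration_s record length, s
#' @param bead_radius_um bead radius, um
#' @param viscosity_pa_s medium viscosity, Pa s
#' @param temperature_k temperature, K
#' @param volts_per_um detector position response, V/um
#' @param detector_noise_v_sd additive Gaussian detector noise (V), default off
#' @param thermal_noise include thermal forcing (FALSE gives the
#'   deterministic response, useful for closed-form checks)
#' @param substeps Euler-Maruyama sub-steps per sample; NULL picks the
#'   smallest value keeping the sub-step below gamma/(40 k_total)
#' @param seed RNG seed
#' @return a \code{SynthTrapConfig} list
#' @export
synth_trap_config <- function(k_trap_pn_um = 74.4, k_spring_true_pn_um = 0.9,
                              drive_amplitude_um = 3, drive_frequency_hz = 1,
                              sampling_rate_hz = 1e4, duration_s = 60,
                              bead_radius_um = 1.71 / 2,
                              viscosity_pa_s = 1e-3,
                              temperature_k = DEFAULT_TEMPERATURE_K,
                              volts_per_um = 1.66, detector_noise_v_sd = 0,
                              thermal_noise = TRUE, substeps = NULL,
                              seed = 1L) {
  cfg <- list(k_trap_pn_um = k_trap_pn_um,
              k_spring_true_pn_um = k_spring_true_pn_um,
              drive_amplitude_um = drive_amplitude_um,
              drive_frequency_hz = drive_frequency_hz,
              sampling_rate_hz = sampling_rate_hz, duration_s = duration_s,
              bead_radius_um = bead_radius_um,
              viscosity_pa_s = viscosity_pa_s, temperature_k = temperature_k,
              volts_per_um = volts_per_um,
              detector_noise_v_sd = detector_noise_v_sd,
              thermal_noise = isTRUE(thermal_noise), substeps = substeps,
              seed = as.integer(seed))
  stopifnot(cfg$k_trap_pn_um > cfg$k_spring_true_pn_um,
            cfg$k_spring_true_pn_um >= 0, cfg$drive_amplitude_um >= 0,
            cfg$drive_frequency_hz > 0, cfg$bead_radius_um > 0,
            cfg$volts_per_um > 0, cfg$temperature_k > 0)
  if (cfg$drive_amplitude_um > 0) {
    stopifnot(cfg$sampling_rate_hz >= 100 * cfg$drive_frequency_hz,
              cfg$duration_s >= 10 / cfg$drive_frequency_hz)
  }
  class(cfg) <- "SynthTrapConfig"
  cfg
}

#' Simulate a driven-bead QPD voltage trace
#'
#' Euler-Maruyama integration of the overdamped bead (drag gamma = 6 pi eta
#' r), restoring force -k_trap x + k_spring (x_p(t) - x), thermal noise of
#' variance 2 k_B T / gamma per unit time. The output grid equals the
#' acquisition grid; integration sub-steps are inserted automatically to
#' respect the stability/accuracy bound.
#'
#' @param config a \code{\link{synth_trap_config}}
#' @return a \code{QPDTrace}: list(t_s, volts, sampling_rate_hz, truth)
#' @export
gen_qpd_trace <- function(config) {
  stopifnot(inherits(config, "SynthTrapConfig"))
  c0 <- config
  gamma <- stokes_drag(c0$bead_radius_um, c0$viscosity_pa_s)
  k_tot <- c0$k_trap_pn_um + c0$k_spring_true_pn_um
  dt <- 1 / c0$sampling_rate_hz
  substeps <- c0$substeps %||% max(1L, ceiling(dt / (gamma / (40 * k_tot))))
  dt_sub <- dt / substeps
  if (dt_sub > gamma / c0$k_trap_pn_um) {
    stop("integration step exceeds the stability bound gamma/k_trap; ",
         "increase substeps or sampling rate")
  }
  n <- round(c0$duration_s * c0$sampling_rate_hz)
  kbt <- if (c0$thermal_noise) kbt_pn_um(c0$temperature_k) else 0
  set.seed(c0$seed)
  x <- ou_simulate_cpp(n, substeps, dt_sub, gamma, c0$k_trap_pn_um,
                       c0$k_spring_true_pn_um, c0$drive_amplitude_um,
                       c0$drive_frequency_hz, kbt, 0)
  volts <- c0$volts_per_um * x
  if (c0$detector_noise_v_sd > 0) {
    volts <- volts + stats::rnorm(n, sd = c0$detector_noise_v_sd)
  }
  qpd_trace(t_s = (seq_len(n) - 1) * dt, volts = volts,
            sampling_rate_hz = c0$sampling_rate_hz,
            truth = list(position_um = x, gamma_pn_s_um = gamma,
                         config = unclass(c0)))
}

#' Construct a QPD voltage trace object
#'
#' @param t_s uniform time grid, s
#' @param volts detector signal, V
#' @param sampling_rate_hz sampling rate, Hz
#' @param truth optional ground-truth list (synthetic traces)
#' @return a \code{QPDTrace}
#' @export
qpd_trace <- function(t_s, volts, sampling_rate_hz, truth = list()) {
  stopifnot(length(t_s) == length(volts), sampling_rate_hz > 0)
  structure(list(t_s = t_s, volts = volts,
                 sampling_rate_hz = sampling_rate_hz, truth = truth),
            class = "QPDTrace")
}

#' @export
print.QPDTrace <- function(x, ...) {
  cat(sprintf("QPDTrace: %d samples, %.4g s at %.4g kHz\n", length(x$volts),
              length(x$volts) / x$sampling_rate_hz,
              x$sampling_rate_hz / 1000))
  invisible(x)
}

#' Write / read a QPD trace as CSV (t_s, volts) with a JSON sidecar
#'
#' @param trace a \code{QPDTrace}
#' @param path CSV path; metadata goes to \code{<path>.json}
#' @return path invisibly (writer); a QPDTrace (reader)
#' @export
write_qpd_csv <- function(trace, path) {
  stopifnot(inherits(trace, "QPDTrace"))
  utils::write.csv(data.frame(t_s = trace$t_s, volts = trace$volts), path,
                   row.names = FALSE)
  jsonlite::write_json(list(sampling_rate_hz = trace$sampling_rate_hz,
                            truth = trace$truth["config"]),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_qpd_csv
#' @export
read_qpd_csv <- function(path) {
  df <- utils::read.csv(path)
  meta_path <- paste0(path, ".json")
  fs <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)$sampling_rate_hz
  } else {
    1 / stats::median(diff(df$t_s))
  }
  qpd_trace(df$t_s, df$volts, fs)
}

#' Render a field of annular protein rings with known brightness and diameter
#'
#' Rings are drawn with a Gaussian rim profile of the PSF width on circles of
#' the requested diameter, normalized so each ring integrates to its drawn
#' brightness. Centres are placed by rejection sampling with a minimum
#' separation of one ring diameter plus 6 PSF sigma; an overcrowded request
#' fails. A truth table (centre, diameter, brightness) is returned alongside
#' the image.
#'
#' @param n_rings number of rings
#' @param diameter_um ring diameter (rim-to-rim), um
#' @param brightness_mean mean integrated brightness per ring (photons)
#' @param brightness_cv coefficient of variation of ring brightness
#' @param field_um side length of the square field, um
#' @param pixel_size_um pixel size, um
#' @param psf_sigma_um rim sigma, um
#' @param background_photons background level
#' @param noise apply Poisson noise
#' @param seed RNG seed
#' @return list(stack = ImageStack, truth = data.frame(x_px, y_px,
#'   diameter_um, brightness))
#' @export
gen_ring_field <- function(n_rings, diameter_um = 0.44, brightness_mean = 5e4,
                           brightness_cv = 0.2, field_um = 15,
                           pixel_size_um = 0.11, psf_sigma_um = 0.15,
                           background_photons = 2, noise = TRUE, seed = 1L) {
  px <- pixel_size_um
  n <- ceiling(field_um / px)
  set.seed(as.integer(seed))
  min_sep_px <- (diameter_um + 6 * psf_sigma_um) / px
  margin_px <- (diameter_um / 2 + 4 * psf_sigma_um) / px + 1
  centers <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(centers) < n_rings) {
    if ((tries <- tries + 1L) > 200L * max(n_rings, 1L)) {
      stop("overcrowded field: cannot place ", n_rings,
           " non-overlapping rings in ", field_um, " um")
    }
    cand <- stats::runif(2, margin_px, n - 1 - margin_px)
    if (nrow(centers) == 0 ||
        all(sqrt(rowSums(sweep(centers, 2, cand)^2)) >= min_sep_px)) {
      centers <- rbind(centers, cand)
    }
  }
  brightness <- brightness_mean *
    pmax(0.05, 1 + brightness_cv * stats::rnorm(n_rings))
  img <- matrix(0, n, n)
  for (i in seq_len(nrow(centers))) {
    img <- img + render_ring(n, centers[i, 1], centers[i, 2],
                             diameter_um / 2 / px, psf_sigma_um / px,
                             brightness[i])
  }
  img <- img + background_photons
  if (noise) img <- matrix(stats::rpois(n * n, img), n, n)
  truth <- data.frame(x_px = centers[, 1], y_px = centers[, 2],
                      diameter_um = rep(diameter_um, n_rings),
                      brightness = brightness)
  list(stack = image_stack(array(img, dim = c(n, n, 1, 1)), px,
                           channels = "protein",
                           truth = list(rings = truth)),
       truth = truth)
}

# Annular Gaussian-rim ring at fractional centre (cx, cy) (0-based),
# radius and rim sigma in px, normalized to integrate to `brightness`.
render_ring <- function(n, cx, cy, radius_px, rim_sigma_px, brightness) {
  half <- ceiling(radius_px + 4 * rim_sigma_px)
  xi <- round(cx); yi <- round(cy)
  xs <- max(0, xi - half):min(n - 1, xi + half)
  ys <- max(0, yi - half):min(n - 1, yi + half)
  rho <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
  k <- exp(-(rho - radius_px)^2 / (2 * rim_sigma_px^2))
  out <- matrix(0, n, n)
  out[ys + 1, xs + 1] <- brightness * k / sum(k)
  out
}
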