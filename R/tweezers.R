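# Optical-trap calibration and oscillation-mode spring-constant estimation.
#
# Calibration: the QPD volts-to-um conversion is the slope of the linear
# core of the s-shaped position response; trap stiffness comes from the
# Lorentzian corner frequency of the undriven power spectrum,
# k_trap = 2 pi gamma f_c. Measurement: the stage oscillates (A = 3 um,
# f = 1 Hz), the FFT amplitude of the QPD signal at the drive frequency is
# converted to force, and the spring constant is force amplitude / A.

#' Volts-per-micrometre conversion from a position scan
#'
#' Extracts the central slope of the s-shaped detector response. Points with
#' |response| below \code{core_fraction} of the saturation level define the
#' core; within it the response is fit as an odd cubic (line plus x^3 term)
#' and the linear coefficient -- the tangent slope at the s-curve centre --
#' is reported. The cubic term absorbs the onset of saturation that would
#' otherwise bias a plain line fit low by several percent; with fewer than 7
#' core points a plain line is fit instead.
#'
#' @param position_um stage positions, um
#' @param volts detector response, V
#' @param core_fraction fraction of the saturation amplitude delimiting the
#'   linear core
#' @return list(volts_per_um, n_core, fit): slope in V/um
#' @export
fit_position_calibration <- function(position_um, volts,
                                     core_fraction = 0.7) {
  stopifnot(length(position_um) == length(volts), length(volts) >= 5)
  v0 <- volts - stats::median(volts)
  sat <- max(abs(v0))
  core <- abs(v0) < core_fraction * sat
  if (sum(core) < 3) stop("no linear region detected in the position scan")
  x0 <- position_um - stats::median(position_um[core])
  fit <- if (sum(core) >= 7) {
    stats::lm(volts ~ x0 + I(x0^3), subset = core)
  } else {
    stats::lm(volts ~ x0, subset = core)
  }
  list(volts_per_um = unname(stats::coef(fit)[2]), n_core = sum(core),
       fit = fit)
}

#' Welch power spectral density
#'
#' Mean of periodograms over Hann-windowed segments with 50% overlap;
#' one-sided density in input-units^2 per Hz, DC excluded.
#'
#' @param x signal
#' @param fs sampling rate, Hz
#' @param segment_s segment length, s
#' @param overlap fractional overlap between segments
#' @return data.frame(freq_hz, power)
#' @export
welch_psd <- function(x, fs, segment_s = 1, overlap = 0.5) {
  nseg <- round(segment_s * fs)
  stopifnot(nseg >= 16, length(x) >= nseg)
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nseg) / (nseg + 1)))   # Hann
  norm <- fs * sum(w^2)
  nf <- floor(nseg / 2)
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)
    acc <- acc + (Mod(X[2:(nf + 1)])^2) / norm
  }
  p <- acc / length(starts)
  p[seq_len(nf - 1)] <- 2 * p[seq_len(nf - 1)]   # one-sided (not Nyquist bin)
  data.frame(freq_hz = (1:nf) * fs / nseg, power = p)
}

#' Trap stiffness from the power spectrum of an undriven trace
#'
#' Fits the Lorentzian S(f) = D / (2 pi^2 (f_c^2 + f^2)) to the Welch
#' spectrum and converts the corner frequency to stiffness via
#' k_trap = 2 pi gamma f_c with Stokes drag gamma = 6 pi eta r. The model
#' includes the aliased copies of the Lorentzian folded into the sampled
#' band (the corner frequency is a sizeable fraction of Nyquist at 10 kHz),
#' and the fit minimizes squared log residuals -- even-handed across the
#' spectrum's decades and insensitive to the skew of periodogram noise.
#' Start values come from the linear regression of 1/S on f^2.
#'
#' @param trace a \code{QPDTrace} (undriven)
#' @param volts_per_um position conversion, V/um
#' @param bead_radius_um bead radius, um
#' @param viscosity_pa_s medium viscosity, Pa s
#' @param temperature_k temperature, K
#' @param fit_range_hz frequency window for the fit; default
#'   c(10, 0.4 fs)
#' @param segment_s Welch segment length, s
#' @param n_alias number of spectral alias terms on each side
#' @return a \code{TrapCalibration}: list(volts_per_um, k_trap_pn_um, f_c_hz,
#'   gamma_pn_s_um, diffusion_um2_s, temperature_k)
#' @export
fit_trap_stiffness <- function(trace, volts_per_um, bead_radius_um = 1.71 / 2,
                               viscosity_pa_s = 1e-3,
                               temperature_k = DEFAULT_TEMPERATURE_K,
                               fit_range_hz = NULL, segment_s = 1,
                               n_alias = 3L) {
  stopifnot(inherits(trace, "QPDTrace"))
  fs <- trace$sampling_rate_hz
  if (length(trace$volts) / fs < 10) {
    stop("trace shorter than 10 s; corner-frequency fit unreliable")
  }
  x_um <- trace$volts / volts_per_um
  psd <- welch_psd(x_um, fs, segment_s = segment_s)
  lf <- fit_lorentzian_psd(psd$freq_hz, psd$power, fs,
                           fit_range_hz = fit_range_hz, n_alias = n_alias)
  f_c <- lf$f_c_hz
  D <- lf$diffusion
  f_low <- min(psd$freq_hz)
  if (f_c > fs / 2 / 2 || f_c < 2 * f_low) {
    stop(sprintf(
      "corner frequency %.1f Hz too close to the resolved band [%.2f, %.0f] Hz",
      f_c, f_low, fs / 2))
  }
  gamma <- stokes_drag(bead_radius_um, viscosity_pa_s)
  structure(list(volts_per_um = volts_per_um,
                 k_trap_pn_um = 2 * pi * gamma * f_c, f_c_hz = f_c,
                 gamma_pn_s_um = gamma, diffusion_um2_s = D,
                 temperature_k = temperature_k),
            class = "TrapCalibration")
}

#' Fit a Lorentzian to a one-sided power spectral density
#'
#' Model S(f) = D / (2 pi^2 (f_c^2 + f^2)), summed over \code{n_alias}
#' folded spectral copies on each side; squared log-residuals are minimized,
#' with start values from the linear regression of 1/S on f^2.
#'
#' @param freq_hz frequencies, Hz
#' @param power one-sided PSD values
#' @param fs sampling rate, Hz (for the alias folding)
#' @param fit_range_hz two-element window; default c(10, 0.4 fs)
#' @param n_alias alias terms on each side (0 = plain Lorentzian)
#' @return list(f_c_hz, diffusion)
#' @export
fit_lorentzian_psd <- function(freq_hz, power, fs, fit_range_hz = NULL,
                               n_alias = 3L) {
  fit_range_hz <- fit_range_hz %||% c(10, 0.4 * fs)
  sel <- freq_hz >= fit_range_hz[1] & freq_hz <= fit_range_hz[2]
  f <- freq_hz[sel]; S <- power[sel]
  stopifnot(length(f) >= 8)
  model <- function(f, D, fc) {
    out <- 0
    for (n in -n_alias:n_alias) {
      out <- out + D / (2 * pi^2 * (fc^2 + (f + n * fs)^2))
    }
    out
  }
  # linearized start: 1/S = (2 pi^2 / D) (f_c^2 + f^2)
  b <- stats::coef(stats::lm(I(1 / S) ~ I(f^2)))
  D0 <- 2 * pi^2 / max(b[2], .Machine$double.eps)
  fc0 <- sqrt(max(b[1], .Machine$double.eps) / max(b[2], .Machine$double.eps))
  obj <- function(p) sum((log(S) - log(model(f, exp(p[1]), exp(p[2]))))^2)
  opt <- stats::optim(c(log(D0), log(fc0)), obj)
  list(f_c_hz = exp(opt$par[2]), diffusion = exp(opt$par[1]))
}

#' Equipartition stiffness cross-check
#'
#' k = k_B T / var(x) from the calibrated positional variance of an undriven
#' trace.
#'
#' @param trace a \code{QPDTrace}
#' @param volts_per_um position conversion, V/um
#' @param temperature_k temperature, K
#' @return stiffness in pN/um
#' @export
equipartition_stiffness <- function(trace, volts_per_um,
                                    temperature_k = DEFAULT_TEMPERATURE_K) {
  x <- trace$volts / volts_per_um
  kbt_pn_um(temperature_k) / stats::var(x)
}

#' Single-sided FFT amplitude at the drive frequency
#'
#' The record is truncated to an integer number of drive periods,
#' mean-subtracted, and the amplitude is 2 |X(f_drive)| / N for the discrete
#' Fourier transform, so a pure sinusoid of amplitude a returns exactly a.
#'
#' @param trace a \code{QPDTrace}
#' @param f_drive_hz drive frequency, Hz
#' @return amplitude in volts
#' @export
fft_drive_amplitude <- function(trace, f_drive_hz = 1) {
  stopifnot(inherits(trace, "QPDTrace"))
  fs <- trace$sampling_rate_hz
  n_periods <- floor(length(trace$volts) * f_drive_hz / fs)
  if (n_periods < 1) stop("record shorter than one drive period")
  N <- round(n_periods * fs / f_drive_hz)
  k <- round(f_drive_hz * N / fs)          # drive bin (exact by construction)
  if (abs(k - f_drive_hz * N / fs) > 1e-9) {
    stop("drive frequency does not fall on the truncated frequency grid")
  }
  x <- trace$volts[seq_len(N)]
  x <- x - mean(x)
  X <- stats::fft(x)
  2 * Mod(X[k + 1]) / N
}

#' Oscillation-mode spring constant
#'
#' x_amp = FFT amplitude / volts_per_um; F_amp = k_trap x_amp;
#' k_spring = F_amp / A. The trap and tube springs act in series, so the
#' estimator carries the factor k_trap/(k_trap + k_true); this bias is
#' documented, not corrected, to mirror the assay's estimator.
#'
#' @param trace a \code{QPDTrace} recorded with the drive on
#' @param calib a \code{\link{fit_trap_stiffness}} result (or list with
#'   volts_per_um and k_trap_pn_um)
#' @param amplitude_um drive amplitude A, um
#' @param frequency_hz drive frequency f, Hz
#' @return a \code{SpringMeasurement}: list(fft_amplitude_volts,
#'   displacement_amplitude_um, force_amplitude_pn, k_spring_pn_um,
#'   saturation_warning)
#' @export
spring_constant <- function(trace, calib, amplitude_um = 3,
                            frequency_hz = 1) {
  stopifnot(amplitude_um > 0, frequency_hz > 0)
  v_amp <- fft_drive_amplitude(trace, frequency_hz)
  x_amp <- v_amp / calib$volts_per_um
  f_amp <- calib$k_trap_pn_um * x_amp
  structure(list(fft_amplitude_volts = v_amp,
                 displacement_amplitude_um = x_amp,
                 force_amplitude_pn = f_amp,
                 k_spring_pn_um = f_amp / amplitude_um,
                 baseline_subtracted = FALSE,
                 saturation_warning = x_amp > 0.5),
            class = "SpringMeasurement")
}

#' Subtract the lipid baseline from protein spring constants
#'
#' Protein measurements falling inside the [min, max] range of the
#' lipid-only set are discarded (the lipid response dominated those
#' vesicles); the protein-only constant is mean(kept) - mean(lipid).
#'
#' @param k_ftsz_samples protein+lipid spring constants, pN/um
#' @param k_lipid_samples lipid-only spring constants, pN/um
#' @return list(k_ftsz_only, k_ftsz_kept_mean, k_lipid_mean, kept (logical
#'   mask), n_discarded, all_discarded)
#' @export
subtract_lipid_baseline <- function(k_ftsz_samples, k_lipid_samples) {
  stopifnot(length(k_ftsz_samples) > 0, length(k_lipid_samples) > 0)
  rng <- range(k_lipid_samples)
  kept <- k_ftsz_samples < rng[1] | k_ftsz_samples > rng[2]
  if (!any(kept)) {
    return(list(k_ftsz_only = NA_real_, k_ftsz_kept_mean = NA_real_,
                k_lipid_mean = mean(k_lipid_samples), kept = kept,
                n_discarded = sum(!kept), all_discarded = TRUE))
  }
  list(k_ftsz_only = mean(k_ftsz_samples[kept]) - mean(k_lipid_samples),
       k_ftsz_kept_mean = mean(k_ftsz_samples[kept]),
       k_lipid_mean = mean(k_lipid_samples), kept = kept,
       n_discarded = sum(!kept), all_discarded = FALSE)
}

#' Force exerted per ring unit
#'
#' F_ring = k_spring * A / n_rings: the total oscillation-mode force
#' amplitude shared over the ring units on the tube.
#'
#' @param k_spring_pn_um spring constant, pN/um
#' @param amplitude_um oscillation amplitude A, um
#' @param n_rings number of ring units on the tube (>= 1)
#' @return force per ring in pN
#' @export
per_ring_force <- function(k_spring_pn_um, amplitude_um, n_rings) {
  if (n_rings < 1) stop("per-ring force undefined for n_rings < 1")
  k_spring_pn_um * amplitude_um / n_rings
}
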