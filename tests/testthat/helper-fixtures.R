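# Shared fixture builders for the test suite. Everything is generated in
# code with fixed seeds; no binary fixtures.

# a trap calibration with known constants (skips the spectral fit when the
# trap stiffness itself is a given, as in the oscillation protocol)
known_calibration <- function(k_trap_pn_um = 74.4, volts_per_um = 1.66) {
  structure(list(volts_per_um = volts_per_um, k_trap_pn_um = k_trap_pn_um,
                 f_c_hz = NA_real_,
                 gamma_pn_s_um = stokes_drag(1.71 / 2),
                 diffusion_um2_s = NA_real_,
                 temperature_k = DEFAULT_TEMPERATURE_K),
            class = "TrapCalibration")
}

# standard helix fixture at a given pitch/seed (assay-like defaults)
helix_stack <- function(pitch_um, seed, ...) {
  gen_helical_tube_stack(synth_tube_config(pitch_um = pitch_um, seed = seed,
                                           ...))
}

# ROI centred on a vortex movie's truth circle
vortex_roi <- function(movie) {
  list(center_xy = movie$truth$center_xy,
       radius_px = movie$truth$ring_radius_um / movie$pixel_size_um,
       radius_um = movie$truth$ring_radius_um)
}

# least-squares sine fit oracle: amplitude of a sinusoid at f in a sampled
# signal, independent of the FFT path
sine_fit_amplitude <- function(x, fs, f_drive) {
  t <- (seq_along(x) - 1) / fs
  fit <- stats::lm(x ~ sin(2 * pi * f_drive * t) + cos(2 * pi * f_drive * t))
  sqrt(sum(stats::coef(fit)[2:3]^2))
}
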