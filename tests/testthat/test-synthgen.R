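# Synthetic generators: ground truth, determinism, photon accounting,
# physical invariants of the Brownian-dynamics trace.

test_that("tube config validation rejects unphysical requests", {
  expect_error(synth_tube_config(pitch_um = -1))
  expect_error(synth_tube_config(protein_coverage = 1.2))
  expect_error(gen_helical_tube_stack(
    synth_tube_config(pitch_um = 0.15, pixel_size_um = 0.11)), "Nyquist")
})

test_that("zero coverage gives a protein channel of pure background", {
  stk <- gen_helical_tube_stack(synth_tube_config(protein_coverage = 0,
                                                  noise = FALSE, seed = 1))
  prot <- get_frame(stk, "protein")
  expect_true(all(prot == stk$truth$config$background_photons))
  expect_gt(max(get_frame(stk, "lipid")), max(prot))
})

test_that("fixed seed means bit-identical output across all generators", {
  a <- gen_helical_tube_stack(synth_tube_config(seed = 7))
  b <- gen_helical_tube_stack(synth_tube_config(seed = 7))
  expect_identical(a$pixels, b$pixels)

  m1 <- gen_vortex_movie(0.08, 0.5, frames = 10, seed = 3)
  m2 <- gen_vortex_movie(0.08, 0.5, frames = 10, seed = 3)
  expect_identical(m1$pixels, m2$pixels)

  q1 <- gen_qpd_trace(synth_trap_config(duration_s = 12, seed = 5))
  q2 <- gen_qpd_trace(synth_trap_config(duration_s = 12, seed = 5))
  expect_identical(q1$volts, q2$volts)

  r1 <- gen_ring_field(4, seed = 9)
  r2 <- gen_ring_field(4, seed = 9)
  expect_identical(r1$stack$pixels, r2$stack$pixels)
})

test_that("noiseless renders integrate to the prescribed photon count", {
  cfg <- synth_tube_config(noise = FALSE, background_photons = 0, seed = 1)
  stk <- gen_helical_tube_stack(cfg)
  total <- cfg$photons_per_pixel * cfg$tube_length_um / cfg$pixel_size_um
  expect_lt(abs(sum(get_frame(stk, "lipid")) / total - 1), 1e-3)

  rf <- gen_ring_field(1, brightness_mean = 4e4, brightness_cv = 0,
                       background_photons = 0, noise = FALSE, seed = 2)
  expect_lt(abs(sum(get_frame(rf$stack)) / rf$truth$brightness[1] - 1), 1e-3)
})

test_that("helix arclength truth matches the quadrature oracle", {
  # oracle: numeric quadrature of the constant 3-d integrand, independent of
  # the generator's formula
  cfg <- synth_tube_config(pitch_um = 1.6, helix_radius_um = 0.4,
                           tube_length_um = 10, seed = 1)
  stk <- gen_helical_tube_stack(cfg)
  oracle <- stats::integrate(function(x) {
    rep(sqrt(1 + (2 * pi * 0.4 / 1.6)^2), length(x))
  }, 0, 10)$value
  expect_equal(stk$truth$arclength_3d_um, oracle, tolerance = 1e-8)
  # projected arclength oracle
  oracle_2d <- stats::integrate(function(x) {
    sqrt(1 + ((2 * pi * 0.4 / 1.6) * cos(2 * pi * x / 1.6))^2)
  }, 0, 10, subdivisions = 2000L)$value
  expect_equal(stk$truth$arclength_2d_um, oracle_2d, tolerance = 1e-6)
})

test_that("long-pitch fixture sits in the low-GTPase regime", {
  stk <- helix_stack(3.5, seed = 1)
  expect_gt(stk$truth$pitch_um, 3)
})

test_that("vortex movie stores tangential speed = |omega| r and direction", {
  mov <- gen_vortex_movie(c(0.086, -0.086), 0.5, initial_angle_rad = c(0, pi),
                          frames = 5, seed = 1)
  expect_equal(mov$truth$tangential_speed_um_s, c(0.043, 0.043))
  static <- gen_vortex_movie(0, 0.5, frames = 4, noise = FALSE, seed = 1)
  expect_identical(static$pixels[, , 1, 1], static$pixels[, , 1, 4])
  expect_error(gen_vortex_movie(0.1, ring_radius_um = 0.1,
                                pixel_size_um = 0.11), "unresolvable")
})

test_that("driven bead with no spring shows only the thermal floor at f_drive", {
  cfg0 <- synth_trap_config(k_spring_true_pn_um = 0, duration_s = 12,
                            seed = 4)
  tr0 <- gen_qpd_trace(cfg0)
  amp0 <- fft_drive_amplitude(tr0, 1) / cfg0$volts_per_um
  cfg1 <- synth_trap_config(k_spring_true_pn_um = 0.9, duration_s = 12,
                            seed = 4)
  amp1 <- fft_drive_amplitude(gen_qpd_trace(cfg1), 1) / cfg1$volts_per_um
  expect_lt(amp0, 0.02 * amp1)
})

test_that("noiseless driven bead matches the two-spring closed form", {
  # oracle: steady state of gamma x' = -k_t x + k_s (A sin wt - x) has
  # amplitude A k_s / sqrt((k_t + k_s)^2 + (w gamma)^2) ~ A k_s/(k_t + k_s)
  cfg <- synth_trap_config(k_spring_true_pn_um = 0.9, thermal_noise = FALSE,
                           duration_s = 12, seed = 1)
  tr <- gen_qpd_trace(cfg)
  amp <- fft_drive_amplitude(tr, 1) / cfg$volts_per_um
  expect_equal(amp, 3 * 0.9 / (74.4 + 0.9), tolerance = 2e-4)
})

test_that("undriven trace satisfies equipartition within 5%", {
  cfg <- synth_trap_config(k_spring_true_pn_um = 0, drive_amplitude_um = 0,
                           duration_s = 60, seed = 2)
  tr <- gen_qpd_trace(cfg)
  var_x <- stats::var(tr$truth$position_um)
  expect_lt(abs(var_x / (kbt_pn_um() / 74.4) - 1), 0.05)
})

test_that("trap config invariants are enforced", {
  expect_error(synth_trap_config(k_trap_pn_um = 1, k_spring_true_pn_um = 2))
  expect_error(synth_trap_config(sampling_rate_hz = 50))
  expect_error(synth_trap_config(duration_s = 3))
  # explicit undersized substepping violates the stability bound
  expect_error(gen_qpd_trace(synth_trap_config(sampling_rate_hz = 1000,
                                               duration_s = 12,
                                               substeps = 1L)),
               "stability")
})

test_that("ring fields respect brightness truth and crowding limits", {
  rf <- gen_ring_field(0, seed = 1, background_photons = 3, noise = FALSE)
  expect_true(all(get_frame(rf$stack) == 3))
  expect_equal(nrow(rf$truth), 0)
  expect_error(gen_ring_field(200, field_um = 5, seed = 1), "overcrowded")
})

test_that("stack and trace text round trips preserve data", {
  stk <- gen_helical_tube_stack(synth_tube_config(tube_length_um = 3,
                                                  seed = 1))
  path <- file.path(tempdir(), "stack.csv")
  write_stack(stk, path)
  back <- read_stack(path)
  expect_equal(back$pixels, stk$pixels)
  expect_equal(back$pixel_size_um, stk$pixel_size_um)
  expect_equal(back$truth$pitch_um, stk$truth$pitch_um)

  tr <- gen_qpd_trace(synth_trap_config(duration_s = 12, seed = 1))
  tpath <- file.path(tempdir(), "trace.csv")
  write_qpd_csv(tr, tpath)
  tback <- read_qpd_csv(tpath)
  expect_equal(tback$volts, tr$volts, tolerance = 1e-12)
  expect_equal(tback$sampling_rate_hz, tr$sampling_rate_hz)
  unlink(c(path, paste0(path, ".json"), tpath, paste0(tpath, ".json")))
})
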