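# Distribution statistics and pipeline orchestration: the two-state pitch
# mixture, morphology proportion tables, and a self-contained synthetic demo
# pipeline producing one consolidated report.

#' Two-component Gaussian mixture fit of pitch values
#'
#' Operationalizes "two pitch states": EM for a two-component normal
#' mixture, initialized from the 25th/75th percentiles, component standard
#' deviations floored to keep degenerate clusters finite. Means are reported
#' sorted ascending; the bimodality verdict requires the mode separation to
#' exceed the pooled within-component standard deviation.
#'
#' @param lambda_values pitch observations, um (>= 6 values)
#' @param max_iter EM iteration cap; non-convergence falls back to a flagged
#'   single-component fit
#' @param tol relative log-likelihood convergence tolerance
#' @return a \code{MixtureFit}: list(weights, means, sds, log_likelihood,
#'   converged, bimodal, n_iter)
#' @export
fit_pitch_mixture <- function(lambda_values, max_iter = 500L, tol = 1e-8) {
  x <- as.numeric(lambda_values)
  stopifnot(length(x) >= 6)
  n <- length(x)
  sd_floor <- max(1e-6, 1e-4 * stats::sd(x))
  mu <- as.numeric(stats::quantile(x, c(0.25, 0.75)))
  if (diff(mu) == 0) mu <- mu + c(-1, 1) * sd_floor
  s <- rep(max(stats::sd(x) / 2, sd_floor), 2)
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    d1 <- w[1] * stats::dnorm(x, mu[1], s[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], s[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r <- d1 / tot
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) <= tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    n1 <- sum(r); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) break      # component collapse
    mu <- c(sum(r * x) / n1, sum((1 - r) * x) / n2)
    s <- c(sqrt(sum(r * (x - mu[1])^2) / n1),
           sqrt(sum((1 - r) * (x - mu[2])^2) / n2))
    s <- pmax(s, sd_floor)
    w <- c(n1, n2) / n
  }
  if (!converged) {
    return(structure(list(weights = 1, means = mean(x), sds = stats::sd(x),
                          log_likelihood = sum(stats::dnorm(x, mean(x),
                                                            stats::sd(x),
                                                            log = TRUE)),
                          converged = FALSE, bimodal = FALSE, n_iter = iter),
                     class = "MixtureFit"))
  }
  ord <- order(mu)
  mu <- mu[ord]; s <- s[ord]; w <- w[ord]
  pooled_sd <- sqrt(sum(w * s^2))
  structure(list(weights = w, means = mu, sds = s, log_likelihood = ll,
                 converged = TRUE, bimodal = diff(mu) > pooled_sd,
                 n_iter = iter),
            class = "MixtureFit")
}

#' @export
print.MixtureFit <- function(x, ...) {
  if (length(x$means) == 2) {
    cat(sprintf(
      "MixtureFit: modes %.3g / %.3g um (w = %.2f / %.2f, sd = %.3g / %.3g), %s\n",
      x$means[1], x$means[2], x$weights[1], x$weights[2], x$sds[1], x$sds[2],
      if (x$bimodal) "bimodal" else "not bimodal"))
  } else {
    cat(sprintf("MixtureFit: single component %.3g um (EM did not converge)\n",
                x$means))
  }
  invisible(x)
}

#' Morphology proportion table with percentages and exact binomial CIs
#'
#' @param counts named integer vector or data.frame(category, count) of
#'   per-category counts for one condition
#' @param conf_int add exact (Clopper-Pearson) binomial 95% CIs
#' @return data.frame: category, count, total, percentage (full precision),
#'   percentage_display (rounded to integer), and optionally ci_lo/ci_hi in
#'   percent
#' @export
morphology_proportions <- function(counts, conf_int = FALSE) {
  if (is.data.frame(counts)) {
    category <- as.character(counts$category)
    count <- counts$count
  } else {
    category <- names(counts) %||% as.character(seq_along(counts))
    count <- as.integer(counts)
  }
  stopifnot(all(count >= 0), all(count == round(count)))
  total <- sum(count)
  if (total == 0) stop("zero total count")
  out <- data.frame(category = category, count = count, total = total,
                    percentage = 100 * count / total)
  out$percentage_display <- floor(out$percentage)   # 21/26 -> "80%" style
  if (conf_int) {
    ci <- t(vapply(count, function(k)
      stats::binom.test(k, total)$conf.int * 100, numeric(2)))
    out$ci_lo <- ci[, 1]; out$ci_hi <- ci[, 2]
  }
  out
}

#' Run the all-synthetic demonstration pipeline
#'
#' Executes synth -> kymo/tube/rings -> trap -> mech -> stats on generated
#' inputs with known ground truth and returns one consolidated, JSON-ready
#' report. Each stage fails atomically: its error is recorded under
#' \code{$status} and later stages that do not depend on it still run.
#'
#' @param seed master seed; all stage seeds derive from it
#' @param out optional path; when given the report is written as JSON
#' @param fast reduce simulation sizes (shorter QPD trace) for quick runs
#' @return report list (invisibly when \code{out} is given)
#' @export
run_pipeline <- function(seed = 1L, out = NULL, fast = FALSE) {
  seed <- as.integer(seed) %% .Machine$integer.max
  report <- list(package = "ftszmech",
                 version = as.character(utils::packageVersion("ftszmech")),
                 seed = seed, status = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      report$status[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  # --- synth + kymo: vortex at the flat-membrane reference speed ----------
  kymo_res <- stage("kymo", {
    mov <- gen_vortex_movie(angular_speed_rad_s = 0.043 / 0.5,
                            ring_radius_um = 0.5, frames = 60,
                            seed = seed + 1L)
    roi <- list(center_xy = mov$truth$center_xy,
                radius_px = mov$truth$ring_radius_um / mov$pixel_size_um,
                radius_um = mov$truth$ring_radius_um)
    ky <- compute_kymograph(mov, roi)
    v <- estimate_velocity(ky)
    list(true_speed_um_s = mov$truth$tangential_speed_um_s[1],
         estimated_speed_um_s = v$speed_um_per_s[1],
         direction = v$direction[1])
  })
  report$kymo <- kymo_res

  # --- tube geometry: compressed helix for pitch, relaxed helix for
  # arclength/diameter (resolvable turn separation) -----------------------
  tube_res <- stage("tube", {
    cfg_c <- synth_tube_config(pitch_um = 1.6, frames = 2,
                               protein_coverage_initial = 0.1,
                               protein_coverage = 0.8, seed = seed + 2L)
    stk_c <- gen_helical_tube_stack(cfg_c)
    lipid_c <- get_frame(stk_c, "lipid", dim(stk_c$pixels)[4])
    pitch <- measure_pitch(lipid_c, stk_c$pixel_size_um)

    cfg_r <- synth_tube_config(pitch_um = 3.5, seed = seed + 7L)
    stk_r <- gen_helical_tube_stack(cfg_r)
    lipid_r <- get_frame(stk_r, "lipid")
    trace <- tube_arclength(lipid_r, stk_r$pixel_size_um)
    dia <- tube_diameter_at_turns(lipid_r, stk_r$pixel_size_um)

    trace_c <- tube_arclength(lipid_c, stk_c$pixel_size_um)
    guv_patch <- matrix(mean(get_frame(stk_c, "protein", 2)[trace_c$mask]),
                        3, 3)
    dens <- protein_density(stk_c, trace_c, guv_patch)
    kappa <- 20 * kbt_pn_um()
    list(true_pitch_um = cfg_c$pitch_um,
         mean_pitch_um = pitch$mean_pitch_um,
         true_arclength_um = stk_r$truth$arclength_2d_um,
         arclength_um = trace$length_um,
         diameter_um = dia$d_um,
         true_diameter_um = stk_r$truth$diameter_observed_um,
         tension_pn_um = if (is.finite(dia$d_um))
           tension_from_diameter(dia$d_um, kappa) else NA_real_,
         density_per_um = dens$density)
  })
  report$tube <- tube_res

  # --- rings: brightness reference and counting --------------------------
  ring_res <- stage("rings", {
    rf <- gen_ring_field(n_rings = 12, diameter_um = 0.44,
                         brightness_mean = 5e4, field_um = 20,
                         seed = seed + 3L)
    img <- get_frame(rf$stack)
    meas <- measure_ring_field(img, rf$truth, box_halfwidth_px = 8L)
    ref <- ring_brightness_reference(meas)
    cnt <- count_rings_on_tube(5 * ref$per_ring_brightness,
                               ref$per_ring_brightness, 5,
                               n_reference_rings = ref$n_used)
    list(per_ring_brightness = ref$per_ring_brightness,
         n_reference = ref$n_used, demo_n_rings = cnt$n_rings,
         demo_rings_per_um = cnt$rings_per_um)
  })
  report$rings <- ring_res

  # --- trap: calibration + driven spring measurement ---------------------
  trap_res <- stage("trap", {
    dur <- if (fast) 20 else 60
    calib_cfg <- synth_trap_config(k_spring_true_pn_um = 0,
                                   drive_amplitude_um = 0, duration_s = dur,
                                   seed = seed + 4L)
    calib_trace <- gen_qpd_trace(calib_cfg)
    calib <- fit_trap_stiffness(calib_trace, calib_cfg$volts_per_um)
    drive_cfg <- synth_trap_config(k_spring_true_pn_um = 0.9,
                                   duration_s = dur, seed = seed + 5L)
    drive_trace <- gen_qpd_trace(drive_cfg)
    meas <- spring_constant(drive_trace, calib,
                            amplitude_um = drive_cfg$drive_amplitude_um,
                            frequency_hz = drive_cfg$drive_frequency_hz)
    f_ring <- per_ring_force(meas$k_spring_pn_um,
                             drive_cfg$drive_amplitude_um, n_rings = 3)
    list(k_trap_pn_um = calib$k_trap_pn_um, f_c_hz = calib$f_c_hz,
         equipartition_k = equipartition_stiffness(calib_trace,
                                                   calib_cfg$volts_per_um),
         k_spring_pn_um = meas$k_spring_pn_um,
         k_spring_series_expected = 0.9 * 74.4 / (74.4 + 0.9),
         per_ring_force_pn = f_ring)
  })
  report$trap <- trap_res

  # --- mechanics: printed-value closed forms -----------------------------
  report$mech <- stage("mech", {
    rod <- rod_parameters(l_p_um = 0.39, r_nm = 2.5)
    cons <- modulus_consistency(0.59, 0.34, rod$E_mpa, 22.9)
    list(K_nm2 = rod$K_nm2, E_mpa = rod$E_mpa,
         k_ratio = cons$k_ratio, E_ratio = cons$E_ratio,
         gtpase_force_pn = gtpase_force_estimate(2, 0.9, 1))
  })

  # --- stats: bimodal pitch states ---------------------------------------
  report$stats <- stage("stats", {
    set.seed(seed + 6L)
    lam <- c(stats::rnorm(100, 1.6, 0.2), stats::rnorm(100, 3.5, 0.4))
    fit <- fit_pitch_mixture(lam)
    morph <- morphology_proportions(c(deformed_neck = 21, other = 5))
    list(mixture_means_um = fit$means, bimodal = fit$bimodal,
         morphology = morph)
  })

  if (!length(report$status)) report$status <- list(ok = TRUE)
  if (!is.null(out)) {
    dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(report))
  }
  report
}
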