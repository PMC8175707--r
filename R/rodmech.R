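# Elastic-rod mechanics linking measured spring constants to filament
# material properties: flexural rigidity K = l_p k_B T, Young's modulus
# E = K / I with I = pi r^4 / 4, the spring-modulus relation E = k l_0 / S,
# and the GTPase-dependent per-ring force estimate. All closed forms work in
# SI internally; pN/um inputs are converted at the boundary.

#' Flexural rigidity from persistence length
#'
#' K = l_p k_B T. For semiflexible filaments the persistence length measures
#' thermal bending decorrelation; multiplying by the thermal energy gives
#' the bending stiffness of the equivalent elastic rod.
#'
#' @param l_p_um persistence length, um
#' @param temperature_k temperature, K
#' @return flexural rigidity K in N m^2
#' @export
flexural_rigidity <- function(l_p_um, temperature_k = DEFAULT_TEMPERATURE_K) {
  stopifnot(all(l_p_um >= 0), temperature_k > 0)
  (l_p_um * 1e-6) * KB_SI * temperature_k
}

#' Area moment of inertia of a solid circular cross-section
#'
#' I = pi r^4 / 4.
#'
#' @param r_m filament radius, m (2.5 nm = 2.5e-9 for a single filament)
#' @return area moment I in m^4
#' @export
area_moment <- function(r_m) {
  stopifnot(all(r_m >= 0))
  pi * r_m^4 / 4
}

#' Young's modulus from flexural rigidity
#'
#' E = K / I (K = E I for a homogeneous elastic rod).
#'
#' @param K_nm2 flexural rigidity, N m^2
#' @param I_m4 area moment, m^4
#' @return Young's modulus in Pa
#' @export
young_modulus_from_rigidity <- function(K_nm2, I_m4) {
  stopifnot(all(I_m4 > 0))
  K_nm2 / I_m4
}

#' Thin-wall hollow-cylinder cross-section area
#'
#' S = 2 pi r_mid t: the cross-section of a thin shell (lipid bilayer ~5 nm,
#' or a monolayer of membrane-bound filaments ~5 nm) wrapped around the
#' tube.
#'
#' @param radius_mid_m mid-shell radius, m
#' @param thickness_m wall thickness, m
#' @return list(S_m2, thin_wall_ok): area in m^2; \code{thin_wall_ok} FALSE
#'   when thickness exceeds the radius (thin-wall formula doubtful)
#' @export
cylinder_section <- function(radius_mid_m, thickness_m) {
  stopifnot(radius_mid_m > 0, thickness_m > 0)
  list(S_m2 = 2 * pi * radius_mid_m * thickness_m,
       thin_wall_ok = thickness_m <= radius_mid_m)
}

#' Young's modulus of a spring from its constant, length and cross-section
#'
#' E = k l_0 / S.
#'
#' @param k_pn_um spring constant, pN/um
#' @param l_0_um spring initial length, um
#' @param S_m2 cross-section area, m^2
#' @return Young's modulus in Pa
#' @export
spring_young_modulus <- function(k_pn_um, l_0_um, S_m2) {
  stopifnot(all(k_pn_um > 0), all(l_0_um > 0), all(S_m2 > 0))
  k_si <- k_pn_um * 1e-6          # pN/um -> N/m
  (k_si * l_0_um * 1e-6) / S_m2
}

#' Consistency between spring-constant and modulus ratios
#'
#' For two coaxial shells with equal l_0/S, E_a/E_b = k_a/k_b; this compares
#' the measured stiffness ratio with the independently derived modulus
#' ratio.
#'
#' @param k_ftsz,k_lipid spring constants, pN/um
#' @param E_ftsz,E_lipid Young's moduli (any common unit)
#' @return list(k_ratio, E_ratio, relative_gap = |k_ratio - E_ratio|/E_ratio)
#' @export
modulus_consistency <- function(k_ftsz, k_lipid, E_ftsz, E_lipid) {
  stopifnot(k_ftsz > 0, k_lipid > 0, E_ftsz > 0, E_lipid > 0)
  k_ratio <- k_ftsz / k_lipid
  E_ratio <- E_ftsz / E_lipid
  list(k_ratio = k_ratio, E_ratio = E_ratio,
       relative_gap = abs(k_ratio - E_ratio) / E_ratio)
}

#' GTPase-attributable force per ring from the pitch difference
#'
#' The spring compression attributable to GTP hydrolysis is read from the
#' pitch difference between the active and hydrolysis-dead states
#' (delta_lambda ~2 um). Taking half the pitch difference as the effective
#' per-ring displacement, the force per ring unit within 1 um of tube is
#' F = k_ref (delta_lambda / 2) / (rings_per_um * 1 um). With the working
#' values (k ~0.9 pN/um, delta_lambda ~2 um, ~1 ring/um) this gives ~0.9 pN.
#' Set \code{full_delta = TRUE} to use the full pitch difference instead
#' (doubles the estimate).
#'
#' @param delta_lambda_um pitch difference, um (>= 0)
#' @param k_ref_pn_um reference spring constant, pN/um
#' @param rings_per_um ring linear density, 1/um (> 0)
#' @param full_delta use delta_lambda instead of delta_lambda/2
#' @return force in pN
#' @export
gtpase_force_estimate <- function(delta_lambda_um, k_ref_pn_um,
                                  rings_per_um, full_delta = FALSE) {
  stopifnot(delta_lambda_um >= 0, k_ref_pn_um > 0)
  if (rings_per_um <= 0) stop("rings_per_um must be positive")
  disp <- if (full_delta) delta_lambda_um else delta_lambda_um / 2
  k_ref_pn_um * disp / rings_per_um
}

#' Full rod-parameter set from persistence length and filament radius
#'
#' Convenience bundle evaluating K = l_p k_B T, I = pi r^4/4 and E = K/I in
#' one call.
#'
#' @param l_p_um persistence length, um
#' @param r_nm filament radius, nm
#' @param temperature_k temperature, K
#' @return a \code{RodParameters}: list(l_p_um, temperature_k, K_nm2, r_nm,
#'   I_m4, E_pa, E_mpa)
#' @export
rod_parameters <- function(l_p_um = 0.39, r_nm = 2.5,
                           temperature_k = DEFAULT_TEMPERATURE_K) {
  K <- flexural_rigidity(l_p_um, temperature_k)
  I <- area_moment(r_nm * 1e-9)
  E <- young_modulus_from_rigidity(K, I)
  structure(list(l_p_um = l_p_um, temperature_k = temperature_k, K_nm2 = K,
                 r_nm = r_nm, I_m4 = I, E_pa = E, E_mpa = E / 1e6),
            class = "RodParameters")
}

#' @export
print.RodParameters <- function(x, ...) {
  cat(sprintf("RodParameters: l_p = %.3g um, T = %g K\n", x$l_p_um,
              x$temperature_k))
  cat(sprintf("  K = %.3g N m^2, I = %.3g m^4 (r = %.3g nm), E = %.3g MPa\n",
              x$K_nm2, x$I_m4, x$r_nm, x$E_mpa))
  invisible(x)
}
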