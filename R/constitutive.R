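#' Hill-type active contractile force density
#'
#' Force density generated by contractile smooth-muscle cells per unit
#' constituent area, as a saturating (Hill) function of the local agonist
#' concentration: `A_c = T_c k^n / (K_d + k^n)`. Monotone in `k`, zero
#' without agonist, saturating at the hyper-responsiveness parameter `T_c`;
#' half-saturation where `k^n = K_d`.
#'
#' @param k Agonist concentration(s), non-negative.
#' @param mat A [material_params()] object.
#' @return Force density in kPa, same length as `k`.
#' @examples
#' active_force_density(c(0, 1), material_params(T_c = 2, K_d = 1, n_hill = 2))
#' @export
active_force_density <- function(k, mat) {
  if (!is.numeric(k) || any(!is.finite(k)) || any(k < 0)) {
    abort_bad_arg("`k` must be finite and non-negative.")
  }
  kn <- k^mat$n_hill
  mat$T_c * kn / (mat$K_d + kn)
}

# vectorised constitutive kernel: extra (deviatoric) stress components and
# the active circumferential/axial terms, given principal stretches and
# volume fractions. Plane strain (lam_z = 1) is the default throughout, but
# the formulas keep lam_z general.
#
# Convention: the constant ground-matrix hydrostatic term is absorbed into
# the Lagrange multiplier so the unstrained reference returns exactly zero.
# Stress *differences*, which are what equilibrium and the fibre stress
# depend on, are unaffected.
.passive_extra_stress <- function(lam_r, lam_th, lam_z,
                                  phi_c, phi_p, phi_e, mat) {
  ca <- cos(mat$alpha)^2
  sa <- sin(mat$alpha)^2
  two_psi1 <- phi_c * mat$c_ground + phi_p * mat$c_neo + phi_e * mat$c_ground
  I4 <- lam_th^2 * ca + lam_z^2 * sa

  # per-family fibre energy derivative dW/dI4, tension-gated (the positive
  # part zeroes the compressed/unrecruited branch)
  e_c <- I4 - 1
  wc <- mat$k1_c * ppart(e_c) * exp(mat$k2_c * e_c * e_c)
  e_e <- I4 - mat$lambda_u^2
  we <- mat$k1_e * ppart(e_e) * exp(mat$k2_e * e_e * e_e)
  fib <- 4 * (phi_c * wc + phi_e * we) # both symmetric helical families

  list(
    Trr_hat = two_psi1 * (lam_r^2 - 1),
    Tth_hat = two_psi1 * (lam_th^2 - 1) + fib * lam_th^2 * ca,
    Tzz_hat = two_psi1 * (lam_z^2 - 1) + fib * lam_z^2 * sa
  )
}

.check_kinematics <- function(lam_r, lam_th, lam_z, tol = 1e-8) {
  if (any(lam_r <= 0) || any(lam_th <= 0) || any(lam_z <= 0)) {
    abort_bad_arg("Principal stretches must be positive.")
  }
  if (any(abs(lam_r * lam_th * lam_z - 1) > tol)) {
    abort_bad_arg("Stretches violate incompressibility (lam_r*lam_th*lam_z must be 1).")
  }
}

.check_fractions <- function(phi_c, phi_p, phi_e) {
  phis <- c(phi_c, phi_p, phi_e)
  if (any(phis < -1e-12) || any(phis > 1 + 1e-12)) {
    abort_bad_arg("Volume fractions must lie in [0, 1].")
  }
}

#' Passive (extra) Cauchy stress of the mixture
#'
#' Volume-fraction-weighted passive stress of the constrained mixture at a
#' set of material points, from the neo-Hookean ground matrices plus the
#' tension-gated exponential fibre terms of the contractile and ECM phases.
#' The ECM fibre term contributes nothing below the recruitment stretch
#' `lambda_u`. Components are reported up to the incompressibility pressure
#' (normalised to vanish in the unstrained reference); only stress
#' differences are mechanically meaningful.
#'
#' @param points A data frame with columns `lam_r`, `lam_th`, `phi_c`,
#'   `phi_p`, `phi_e` and optionally `lam_z` (default 1, plane strain).
#' @param mat A [material_params()] object.
#' @return The input as a tibble with columns `Trr_hat`, `Tth_hat`,
#'   `Tzz_hat` appended (kPa).
#' @export
passive_stress_deviatoric <- function(points, mat) {
  points <- tibble::as_tibble(points)
  if (!"lam_z" %in% names(points)) points$lam_z <- 1
  .check_kinematics(points$lam_r, points$lam_th, points$lam_z)
  .check_fractions(points$phi_c, points$phi_p, points$phi_e)
  s <- .passive_extra_stress(points$lam_r, points$lam_th, points$lam_z,
                             points$phi_c, points$phi_p, points$phi_e, mat)
  points$Trr_hat <- s$Trr_hat
  points$Tth_hat <- s$Tth_hat
  points$Tzz_hat <- s$Tzz_hat
  points
}

#' Total Cauchy stress and fibre-direction stress
#'
#' Assembles the total stress `T = -p 1 + T_passive + T_active` at a set of
#' material points and projects it on the two symmetric helical
#' contractile-fibre families to give the mechanotransduction signal
#' `tau = T_thth cos^2(alpha) + T_zz sin^2(alpha)`. The active stress splits
#' the contractile force density over the two families, so its
#' circumferential and axial shares are `phi_c A_c cos^2(alpha)` and
#' `phi_c A_c sin^2(alpha)`.
#'
#' @inheritParams passive_stress_deviatoric
#' @param points Additionally requires a `k` column (agonist concentration);
#'   an optional `p_lagrange` column supplies the incompressibility pressure
#'   (default 0).
#' @return Tibble with columns `Trr`, `Tth`, `Tzz`, `tau` appended (kPa).
#' @export
total_stress <- function(points, mat) {
  points <- passive_stress_deviatoric(points, mat)
  if (!"k" %in% names(points)) points$k <- 0
  if (!"p_lagrange" %in% names(points)) points$p_lagrange <- 0
  ca <- cos(mat$alpha)^2
  sa <- sin(mat$alpha)^2
  act <- points$phi_c * active_force_density(points$k, mat)
  points$Trr <- -points$p_lagrange + points$Trr_hat
  points$Tth <- -points$p_lagrange + points$Tth_hat + act * ca
  points$Tzz <- -points$p_lagrange + points$Tzz_hat + act * sa
  points$tau <- points$Tth * ca + points$Tzz * sa
  points
}
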