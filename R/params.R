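#' Hyperelastic and active material parameters
#'
#' Container for the constitutive parameters of the airway wall mixture.
#' Each solid constituent carries a neo-Hookean ground matrix; the
#' contractile smooth-muscle and collagen (ECM) phases additionally carry two
#' symmetric helical fibre families with an exponential stiffening energy.
#' Collagen fibres are crimped at rest and only bear load once the fibre
#' stretch exceeds the recruitment stretch `lambda_u`. Active contraction is
#' a Hill-type saturating function of agonist concentration with maximal
#' force density `T_c` (the hyper-responsiveness parameter).
#'
#' @param c_ground Ground-matrix stiffness (kPa, per unit constituent
#'   volume), shared by the contractile and ECM phases.
#' @param c_neo Neo-Hookean stiffness (kPa) of the proliferative phase.
#' @param k1_c,k2_c Contractile-fibre exponential coefficients (kPa,
#'   dimensionless).
#' @param k1_e,k2_e ECM collagen-fibre exponential coefficients.
#' @param lambda_u ECM collagen recruitment stretch (>= 1, dimensionless).
#' @param alpha Helical fibre angle from the circumferential direction
#'   (radians, in `[0, pi/2)`).
#' @param T_c Maximal contractile force density (kPa).
#' @param K_d Agonist dissociation constant (concentration^n units).
#' @param n_hill Hill coefficient (> 0).
#'
#' @return A list of class `material_params`.
#' @examples
#' mat <- material_params(T_c = 2, K_d = 1, n_hill = 2)
#' active_force_density(3, mat) # 2 * 9 / 10
#' @export
material_params <- function(c_ground = 4, c_neo = 4,
                            k1_c = 2, k2_c = 1,
                            k1_e = 8, k2_e = 3,
                            lambda_u = 1.3,
                            alpha = 5 * pi / 180,
                            T_c = 20, K_d = 0.5, n_hill = 2) {
  check_number(c_ground, "c_ground", lower = 0)
  check_number(c_neo, "c_neo", lower = 0)
  check_number(k1_c, "k1_c", lower = 0)
  check_number(k2_c, "k2_c", lower = 0, strict_lower = TRUE)
  check_number(k1_e, "k1_e", lower = 0)
  check_number(k2_e, "k2_e", lower = 0, strict_lower = TRUE)
  check_number(lambda_u, "lambda_u", lower = 1)
  check_number(alpha, "alpha", lower = 0, upper = pi / 2 - 1e-12)
  check_number(T_c, "T_c", lower = 0)
  check_number(K_d, "K_d", lower = 0, strict_lower = TRUE)
  check_number(n_hill, "n_hill", lower = 0, strict_lower = TRUE)
  structure(
    list(c_ground = c_ground, c_neo = c_neo,
         k1_c = k1_c, k2_c = k2_c, k1_e = k1_e, k2_e = k2_e,
         lambda_u = lambda_u, alpha = alpha,
         T_c = T_c, K_d = K_d, n_hill = n_hill),
    class = "material_params"
  )
}

#' Biochemical rate parameters for constituent turnover
#'
#' Rates governing smooth-muscle phenotype switching, proliferation,
#' apoptosis and ECM turnover. Inflammation modulates the
#' contractile-to-proliferative switching rate and ECM deposition through a
#' three-tier (healthy / mild / severe) step function with thresholds
#' `mu_1 < mu_2`; fibre-direction stress modulates switching (coefficient
#' `c_cp_f`) and proliferation (`c_p_f`), gated to either tensile or
#' compressive stress via `switch_mode` / `prolif_mode`.
#'
#' The homeostatic volume-fraction partition must fill the solid fraction
#' `1 - phi_w`. By default the baseline ECM deposition rate `c_e0` is
#' re-solved from the steady-state balance so that the partition closes
#' exactly; supply `c_e0` explicitly to override (a warning is then issued
#' by [homeostatic_state()] if the partition does not close).
#'
#' All rates are per day; `tau` enters in kPa.
#'
#' @param c_pc Proliferative-to-contractile switch-back rate (1/day).
#' @param c_p0 Baseline proliferation (or progenitor recruitment) rate
#'   (1/day). Must satisfy `c_pc > c_p0` for a positive steady state.
#' @param c_a Apoptosis coefficient (quadratic in contractile density). The
#'   default places the homeostatic contractile fraction at 0.12.
#' @param c_c0,c_c1,c_c2 Healthy / mild / severe contractile-to-proliferative
#'   switching rates (1/day).
#' @param mu_1,mu_2 Inflammation tier thresholds (dimensionless).
#' @param c_cp_f Stress-modulated switching coefficient (1/(day kPa)).
#' @param switch_mode `"tension"` or `"compression"`: which sign of fibre
#'   stress accelerates phenotype switching. In compressive mode the rate
#'   increment uses the stress magnitude, so it is always non-negative.
#' @param c_p_f Stress-modulated proliferation coefficient (1/(day kPa)).
#' @param prolif_mode As `switch_mode`, for proliferation.
#' @param c_pe ECM synthesis rate by proliferative cells (1/day).
#' @param c_e0,c_e1,c_e2 Healthy / mild / severe inflammation-tiered ECM
#'   deposition rates (mass/(volume day)). `NULL` entries are derived:
#'   `c_e0` from the homeostatic balance, `c_e1 = 2 c_e0`, `c_e2 = 4 c_e0`.
#' @param c_de ECM degradation rate (1/day).
#' @param rho_T Shared true density of the solid constituents
#'   (mass/volume). Defaults to 1 so mass units are absorbed into rates.
#' @param phi_w Fluid (hydration) fraction, constant and uniform.
#'
#' @return A list of class `rate_params`.
#' @seealso [homeostatic_state()]
#' @export
rate_params <- function(c_pc = 1, c_p0 = 0.1,
                        c_a = c_p0 * c_c0 / ((c_pc - c_p0) * 0.12 * rho_T),
                        c_c0 = 0.06, c_c1 = 0.1, c_c2 = 0.2,
                        mu_1 = 0.5, mu_2 = 1.5,
                        c_cp_f = 0.05, switch_mode = c("tension", "compression"),
                        c_p_f = 0, prolif_mode = c("tension", "compression"),
                        c_pe = 0.1,
                        c_e0 = NULL, c_e1 = NULL, c_e2 = NULL,
                        c_de = 0.1, rho_T = 1, phi_w = 0.7) {
  switch_mode <- match.arg(switch_mode)
  prolif_mode <- match.arg(prolif_mode)
  for (nm in c("c_pc", "c_p0", "c_c0", "c_c1", "c_c2", "c_cp_f",
               "c_p_f", "c_pe", "c_de")) {
    check_number(get(nm), nm, lower = 0)
  }
  # validated before the apoptosis default (which divides by c_pc - c_p0)
  # is forced
  if (c_pc <= c_p0) {
    rlang::abort(
      sprintf("`c_pc` (%g) must exceed `c_p0` (%g) for a positive homeostatic state.",
              c_pc, c_p0),
      class = "airwaymorph_steady_state_error"
    )
  }
  check_number(c_a, "c_a", lower = 0, strict_lower = TRUE)
  check_number(rho_T, "rho_T", lower = 0, strict_lower = TRUE)
  check_number(phi_w, "phi_w", lower = 1e-12, upper = 1 - 1e-12)
  if (mu_1 >= mu_2) abort_bad_arg("`mu_1` must be < `mu_2`.")

  phi_c <- c_p0 * c_c0 / (c_a * (c_pc - c_p0) * rho_T)
  phi_p <- phi_c * c_c0 / (c_pc - c_p0)
  if (is.null(c_e0)) {
    # close the homeostatic partition: phi_e* = (1 - phi_w) - phi_c* - phi_p*
    phi_e <- (1 - phi_w) - phi_c - phi_p
    if (phi_e <= 0) {
      rlang::abort(
        "ASM homeostatic fractions already exceed the solid fraction; cannot derive `c_e0`.",
        class = "airwaymorph_steady_state_error"
      )
    }
    c_e0 <- rho_T * (c_de * phi_e - c_pe * phi_p)
    if (c_e0 < 0) {
      rlang::abort(
        "Derived `c_e0` is negative; decrease `c_pe` or increase `c_de`.",
        class = "airwaymorph_steady_state_error"
      )
    }
  }
  if (is.null(c_e1)) c_e1 <- 2 * c_e0
  if (is.null(c_e2)) c_e2 <- 4 * c_e0
  check_number(c_e0, "c_e0", lower = 0)
  check_number(c_e1, "c_e1", lower = 0)
  check_number(c_e2, "c_e2", lower = 0)

  structure(
    list(c_pc = c_pc, c_p0 = c_p0, c_a = c_a,
         c_c0 = c_c0, c_c1 = c_c1, c_c2 = c_c2,
         mu_1 = mu_1, mu_2 = mu_2,
         c_cp_f = c_cp_f, switch_mode = switch_mode,
         c_p_f = c_p_f, prolif_mode = prolif_mode,
         c_pe = c_pe, c_e0 = c_e0, c_e1 = c_e1, c_e2 = c_e2,
         c_de = c_de, rho_T = rho_T, phi_w = phi_w),
    class = "rate_params"
  )
}

#' Global and local stimulus rate parameters
#'
#' Rates governing the global inflammatory status `mu` and the local
#' contractile agonist field `k`: challenge magnitudes (`a_mu`, `a_k`),
#' first-order clearance rates (`c_dmu`, `c_dk`), inflammation-induced
#' agonist release (`a_kmu`) and tensile-stress-induced (mechanotransductive)
#' agonist release (`a_c`).
#'
#' @param a_mu Inflammation challenge magnitude (1/day).
#' @param c_dmu Inflammation clearance rate (1/day).
#' @param a_k Agonist challenge magnitude (concentration/day).
#' @param c_dk Agonist clearance rate (1/day).
#' @param a_kmu Inflammation-induced agonist release rate
#'   (concentration/day per unit `mu`).
#' @param a_c Stress-induced agonist release rate
#'   (concentration/(day kPa)); only tensile fibre stress contributes.
#' @return A list of class `stimulus_params`.
#' @export
stimulus_params <- function(a_mu = 1, c_dmu = 1, a_k = 1, c_dk = 1,
                            a_kmu = 0.1, a_c = 0.01) {
  for (nm in c("a_mu", "c_dmu", "a_k", "c_dk", "a_kmu", "a_c")) {
    check_number(get(nm), nm, lower = 0)
  }
  structure(
    list(a_mu = a_mu, c_dmu = c_dmu, a_k = a_k, c_dk = c_dk,
         a_kmu = a_kmu, a_c = a_c),
    class = "stimulus_params"
  )
}

#' Homeostatic (healthy steady-state) volume fractions
#'
#' Closed-form non-trivial steady state of the well-mixed constituent
#' balance, used as the initial condition of every simulation: phenotype
#' switching, proliferation, apoptosis and ECM turnover balance exactly so
#' that all source terms vanish and no growth occurs.
#'
#' @param rates A [rate_params()] object.
#' @param tol Tolerance for the solid-fraction partition warning.
#' @return Named numeric vector `c(phi_c, phi_p, phi_e)`.
#' @examples
#' phi <- homeostatic_state(rate_params())
#' sum(phi) # 0.30 = 1 - phi_w
#' @export
homeostatic_state <- function(rates, tol = 1e-8) {
  if (rates$c_pc <= rates$c_p0) {
    rlang::abort("No positive steady state: `c_pc` must exceed `c_p0`.",
                 class = "airwaymorph_steady_state_error")
  }
  phi_c <- rates$c_p0 * rates$c_c0 /
    (rates$c_a * (rates$c_pc - rates$c_p0) * rates$rho_T)
  phi_p <- phi_c * rates$c_c0 / (rates$c_pc - rates$c_p0)
  phi_e <- (rates$c_pe * phi_p + rates$c_e0 / rates$rho_T) / rates$c_de
  total <- phi_c + phi_p + phi_e
  if (abs(total - (1 - rates$phi_w)) > tol) {
    rlang::warn(sprintf(
      "Homeostatic fractions sum to %.6f, not the solid fraction %.6f; tune the rates.",
      total, 1 - rates$phi_w
    ))
  }
  c(phi_c = phi_c, phi_p = phi_p, phi_e = phi_e)
}

#' @export
print.material_params <- function(x, ...) {
  cat("<material_params>\n")
  print(unlist(x))
  invisible(x)
}

#' @export
print.rate_params <- function(x, ...) {
  cat("<rate_params>\n")
  nums <- vapply(x, is.numeric, logical(1))
  print(unlist(x[nums]))
  cat("switch_mode:", x$switch_mode, " prolif_mode:", x$prolif_mode, "\n")
  invisible(x)
}

#' @export
print.stimulus_params <- function(x, ...) {
  cat("<stimulus_params>\n")
  print(unlist(x))
  invisible(x)
}
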