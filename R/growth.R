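#' Inflammation- and stress-modulated phenotype switching rate
#'
#' Contractile-to-proliferative switching rate: a three-tier base rate
#' (healthy/mild/severe, thresholds crossed by strict inequality) plus a
#' stress-modulated term. In tension mode the increment is
#' `c_cp_f * tau * H(tau)`; in compression mode the stress magnitude is used
#' (`c_cp_f * (-tau) * H(-tau)`) so the added rate is non-negative.
#'
#' @param mu Inflammatory status (scalar).
#' @param tau Fibre-direction stress (kPa), vectorised.
#' @param rates A [rate_params()].
#' @return Switching rate(s), 1/day, non-negative.
#' @export
switching_rate <- function(mu, tau, rates) {
  base <- rates$c_c0 +
    (rates$c_c1 - rates$c_c0) * h_pos(mu - rates$mu_1) +
    (rates$c_c2 - rates$c_c1) * h_pos(mu - rates$mu_2)
  s <- if (rates$switch_mode == "tension") ppart(tau) else ppart(-tau)
  out <- base + rates$c_cp_f * s
  if (any(out < 0)) {
    rlang::warn("Negative switching rate clipped to 0.")
    out <- pmax(out, 0)
  }
  out
}

#' Stress-modulated proliferation rate
#'
#' `c_p(tau) = c_p0 + c_p_f * |tau|` gated to tensile or compressive fibre
#' stress according to `prolif_mode`.
#'
#' @inheritParams switching_rate
#' @return Proliferation rate(s), 1/day.
#' @export
proliferation_rate <- function(tau, rates) {
  s <- if (rates$prolif_mode == "tension") ppart(tau) else ppart(-tau)
  out <- rates$c_p0 + rates$c_p_f * s
  if (any(out < 0)) {
    rlang::warn("Negative proliferation rate clipped to 0.")
    out <- pmax(out, 0)
  }
  out
}

#' Inflammation-tiered ECM deposition rate
#'
#' @inheritParams switching_rate
#' @return Deposition rate (mass/(volume day)).
#' @export
ecm_deposition_rate <- function(mu, rates) {
  rates$c_e0 +
    (rates$c_e1 - rates$c_e0) * h_pos(mu - rates$mu_1) +
    (rates$c_e2 - rates$c_e1) * h_pos(mu - rates$mu_2)
}

# vectorised source kernel (volume-fraction form, 1/day)
.source_terms <- function(phi_c, phi_p, phi_e, mu, tau, rates) {
  c_cp <- switching_rate(mu, tau, rates)
  c_p <- proliferation_rate(tau, rates)
  c_be <- ecm_deposition_rate(mu, rates)
  list(
    S_c = rates$c_pc * phi_p - rates$c_a * rates$rho_T * phi_c^2 - c_cp * phi_c,
    S_p = (c_p - rates$c_pc) * phi_p + c_cp * phi_c,
    S_e = rates$c_pe * phi_p + c_be / rates$rho_T - rates$c_de * phi_e
  )
}

#' Constituent source terms
#'
#' Net production rates of the contractile, proliferative and ECM volume
#' fractions from phenotype switching, logistic apoptosis, proliferation
#' and ECM turnover. At the homeostatic state with `mu = tau = 0` all three
#' vanish.
#'
#' @param fields A data frame with columns `phi_c`, `phi_p`, `phi_e` and
#'   optionally `tau` (kPa, default 0).
#' @param mu Inflammatory status (scalar).
#' @param rates A [rate_params()].
#' @return The input as a tibble with `S_c`, `S_p`, `S_e` (1/day) appended.
#' @export
source_terms <- function(fields, mu = 0, rates = rate_params()) {
  fields <- tibble::as_tibble(fields)
  if (!"tau" %in% names(fields)) fields$tau <- 0
  s <- .source_terms(fields$phi_c, fields$phi_p, fields$phi_e,
                     mu, fields$tau, rates)
  fields$S_c <- s$S_c
  fields$S_p <- s$S_p
  fields$S_e <- s$S_e
  fields
}

#' Mixture dilatation rate
#'
#' Volumetric growth rate of the saturated mixture,
#' `q = (S_c + S_p + S_e) / (1 - phi_w)`: net solid production is
#' accommodated by proportional expansion at constant hydration.
#'
#' @param S_c,S_p,S_e Constituent source terms (1/day).
#' @param rates A [rate_params()] (supplies `phi_w`).
#' @return `q` (1/day), vectorised.
#' @export
mixture_dilatation <- function(S_c, S_p, S_e, rates) {
  (S_c + S_p + S_e) / (1 - rates$phi_w)
}

#' Radial growth velocity of material points
#'
#' Integrates the dilatation constraint `(1/xi) d(xi v)/dxi = q` inward
#' from the outer wall, where the growth velocity is pinned to zero (all
#' growth is inward): `v(xi) = -(1/xi) int_xi^xi2 zeta q dzeta`. Velocity
#' continuity at the layer interface is automatic.
#'
#' @param q Dilatation field: list with `inner`/`outer` nodal vectors
#'   (1/day), or a scalar applied to both layers.
#' @param geom A [grown_geometry()].
#' @return List with `inner`/`outer` nodal velocities (mm/day);
#'   `v(xi2) = 0` exactly.
#' @export
growth_velocity <- function(q, geom) {
  if (!is.list(q)) {
    q <- list(inner = rep(q, length(geom$xi_in)),
              outer = rep(q, length(geom$xi_out)))
  }
  # J(xi) = int_xi^xi2 zeta q dzeta, accumulated outer -> inner
  cum_out <- cumtrap(geom$xi_out, geom$xi_out * q$outer)
  J_out <- utils::tail(cum_out, 1) - cum_out
  cum_in <- cumtrap(geom$xi_in, geom$xi_in * q$inner)
  J_in <- (utils::tail(cum_in, 1) - cum_in) + J_out[1]
  list(inner = -J_in / geom$xi_in, outer = -J_out / geom$xi_out)
}

#' Advance volume fractions and grown radii by one growth step
#'
#' Lagrangian (material-point) update of the constituent advection-reaction
#' balance: on material points the balance reduces to
#' `dPhi_a/dt = S_a - Phi_a q` and `dxi/dt = v`, so the advective term and
#' the zero-flux boundary conditions are satisfied identically. The forward
#' Euler update preserves the solid-fraction sum exactly (the discrete sum
#' obeys the same fixed point as the continuous one). The outer grown
#' radius stays pinned at `R2`.
#'
#' @param fields A [constituent_fields()] object.
#' @param geom A [grown_geometry()].
#' @param sources Per-layer source terms: components `inner`/`outer`, each
#'   a list with nodal `S_c`, `S_p`, `S_e` (1/day).
#' @param q Per-layer dilatation list.
#' @param v Per-layer growth-velocity list from [growth_velocity()].
#' @param dt Step (days).
#' @return List with updated `fields` and `geom`. A non-monotone updated
#'   grid aborts with a grid-tangling error.
#' @export
advance_growth <- function(fields, geom, sources, q, v, dt) {
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  upd <- function(l, s, qq) {
    list(phi_c = l$phi_c + dt * (s$S_c - l$phi_c * qq),
         phi_p = l$phi_p + dt * (s$S_p - l$phi_p * qq),
         phi_e = l$phi_e + dt * (s$S_e - l$phi_e * qq))
  }
  fields$inner <- upd(fields$inner, sources$inner, q$inner)
  fields$outer <- upd(fields$outer, sources$outer, q$outer)
  xi_in <- geom$xi_in + dt * v$inner
  xi_out <- geom$xi_out + dt * v$outer
  xi_out[length(xi_out)] <- geom$R2
  # conform interface node exactly (shared material point)
  xi_in[length(xi_in)] <- xi_out[1]
  geom$xi_in <- xi_in
  geom$xi_out <- xi_out
  validate_geometry(geom)
  list(fields = fields, geom = geom)
}
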