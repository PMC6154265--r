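# shared fixtures and independent oracles, built in code at test time

small_geom <- function(n = 31) {
  grown_geometry(n_inner = n, n_outer = n)
}

# uniform single-material tube: same mixture in both layers, so the
# two-layer solver degenerates to a homogeneous cylinder
uniform_fields <- function(geom, phi_c = 0, phi_p = 0.3, phi_e = 0,
                           phi_w = 0.7) {
  constituent_fields(geom, phi_c, phi_p, phi_e, phi_w = phi_w,
                     inner_ecm_only = FALSE)
}

# independent quadrature oracle for inflation of a homogeneous
# incompressible neo-Hookean tube (plane strain): adaptive quadrature of
# the classical identity P1 - P2 = int_{r1}^{r2} (Tth - Trr) / r dr,
# root-found on r1 to high precision.
oracle_neohookean_r1 <- function(P1, geom, phi_p, c_neo, P2 = 0,
                                 tol = 1e-12) {
  xi_a <- geom$xi_in[1]
  xi_b <- tail(geom$xi_out, 1)
  G <- function(r1) {
    r2 <- sqrt(r1^2 + xi_b^2 - xi_a^2)
    integrand <- function(r) {
      xi <- sqrt(r^2 - r1^2 + xi_a^2)
      lth <- r / xi
      phi_p * c_neo * (lth^2 - 1 / lth^2) / r
    }
    stats::integrate(integrand, r1, r2, rel.tol = 1e-12,
                     abs.tol = 1e-14)$value - (P1 - P2)
  }
  stats::uniroot(G, c(xi_a * 0.999999, 4 * xi_a), tol = tol)$root
}

# mixture strain energy per unit volume (independent re-implementation for
# finite-difference verification of the analytic stress components)
oracle_mixture_energy <- function(lam_th, lam_z, phi_c, phi_p, phi_e, mat) {
  lam_r <- 1 / (lam_th * lam_z)
  I1 <- lam_r^2 + lam_th^2 + lam_z^2
  I4 <- lam_th^2 * cos(mat$alpha)^2 + lam_z^2 * sin(mat$alpha)^2
  wfib <- function(k1, k2, off) {
    e <- I4 - off
    if (e > 0) k1 / (2 * k2) * (exp(k2 * e^2) - 1) else 0
  }
  (phi_c * mat$c_ground + phi_p * mat$c_neo + phi_e * mat$c_ground) / 2 *
    (I1 - 3) +
    2 * phi_c * wfib(mat$k1_c, mat$k2_c, 1) +
    2 * phi_e * wfib(mat$k1_e, mat$k2_e, mat$lambda_u^2)
}

# density-form constituent turnover, an independent route to the source
# terms (works in rho = phi * rho_T and divides at the end)
oracle_sources <- function(phi_c, phi_p, phi_e, mu, tau, rates) {
  rho_c <- phi_c * rates$rho_T
  rho_p <- phi_p * rates$rho_T
  rho_e <- phi_e * rates$rho_T
  H <- function(x) as.numeric(x > 0)
  c_cp <- rates$c_c0 + (rates$c_c1 - rates$c_c0) * H(mu - rates$mu_1) +
    (rates$c_c2 - rates$c_c1) * H(mu - rates$mu_2) +
    rates$c_cp_f * (if (rates$switch_mode == "tension") pmax(tau, 0)
                    else pmax(-tau, 0))
  c_p <- rates$c_p0 + rates$c_p_f *
    (if (rates$prolif_mode == "tension") pmax(tau, 0) else pmax(-tau, 0))
  c_be <- rates$c_e0 + (rates$c_e1 - rates$c_e0) * H(mu - rates$mu_1) +
    (rates$c_e2 - rates$c_e1) * H(mu - rates$mu_2)
  s_c <- rates$c_pc * rho_p - rates$c_a * rho_c^2 - c_cp * rho_c
  s_p <- (c_p - rates$c_pc) * rho_p + c_cp * rho_c
  s_e <- rates$c_pe * rho_p + c_be - rates$c_de * rho_e
  list(S_c = s_c / rates$rho_T, S_p = s_p / rates$rho_T,
       S_e = s_e / rates$rho_T)
}

# right-hand side of the well-mixed turnover system (volume fractions on a
# single material point), for ODE-solver cross-checks
wellmixed_rhs <- function(phi, rates, mu = 0, tau = 0) {
  s <- oracle_sources(phi[1], phi[2], phi[3], mu, tau, rates)
  q <- (s$S_c + s$S_p + s$S_e) / (1 - rates$phi_w)
  c(s$S_c - phi[1] * q, s$S_p - phi[2] * q, s$S_e - phi[3] * q)
}
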