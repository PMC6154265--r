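#' Pressure load case
#'
#' @param P1 Luminal pressure (kPa).
#' @param P2 External pressure (kPa), default 0; the transmural pressure is
#'   `P1 - P2`.
#' @return A list of class `load_case`.
#' @export
load_case <- function(P1 = 0, P2 = 0) {
  check_number(P1, "P1")
  check_number(P2, "P2")
  structure(list(P1 = P1, P2 = P2), class = "load_case")
}

# circumferential-minus-radial stress difference (passive + active), per
# layer, on the material grid; the Lagrange multiplier cancels in this
# difference, which is all the radial equilibrium integral needs.
.stress_difference <- function(xi, r, phi, k, mat) {
  lam_th <- r / xi
  lam_r <- xi / r
  s <- .passive_extra_stress(lam_r, lam_th, 1,
                             phi$phi_c, phi$phi_p, phi$phi_e, mat)
  act <- phi$phi_c * active_force_density(k, mat) * cos(mat$alpha)^2
  list(diff = s$Tth_hat - s$Trr_hat + act, hat = s)
}

# residual of the outer pressure boundary condition for a trial inner
# radius; optionally returns full profiles
.equilibrium_residual <- function(r1, geom, fields, k, loads, mat,
                                  profile = FALSE, weights = NULL) {
  r <- .map_radii(r1, geom)
  d_in <- .stress_difference(geom$xi_in, r$r_in, fields$inner, k$inner, mat)
  d_out <- .stress_difference(geom$xi_out, r$r_out, fields$outer, k$outer, mat)
  # dT_rr/dxi = (T_thth - T_rr) * xi / r^2  (since dr/dxi = xi/r)
  g_in <- d_in$diff * geom$xi_in / r$r_in^2
  g_out <- d_out$diff * geom$xi_out / r$r_out^2
  if (!profile && !is.null(weights)) {
    return(-loads$P1 + sum(weights$w_in * g_in) +
             sum(weights$w_out * g_out) + loads$P2)
  }
  I_in <- cumquad(geom$xi_in, g_in)
  I_out <- cumquad(geom$xi_out, g_out)
  Trr_in <- -loads$P1 + I_in
  Trr_out <- utils::tail(Trr_in, 1) + I_out
  res <- utils::tail(Trr_out, 1) + loads$P2
  if (!profile) return(res)
  list(res = res, r = r, Trr_in = Trr_in, Trr_out = Trr_out,
       d_in = d_in, d_out = d_out)
}

#' Quasi-static elastic equilibrium of the grown airway
#'
#' Solves radial equilibrium of the two-layer incompressible cylinder under
#' luminal/external pressures and active smooth-muscle tone by shooting on
#' the current inner radius: the radial momentum balance is integrated
#' across the wall (the incompressibility pressure cancels in the
#' circumferential-radial stress difference) and the inner radius is
#' root-found so the outer traction condition is met. Profiles of all
#' stress components, the Lagrange multiplier and the fibre-direction
#' stress are recovered afterwards.
#'
#' @param geom A [grown_geometry()].
#' @param fields A [constituent_fields()] object.
#' @param k Agonist field: scalar, or a list with `inner`/`outer` nodal
#'   vectors as returned internally by the simulator.
#' @param loads A [load_case()].
#' @param mat A [material_params()].
#' @param r1_init Optional warm-start inner radius (mm).
#' @param closure_radius Lumen radius below which the airway is flagged
#'   closed (mm).
#' @param tol Root-finding tolerance on the inner radius (mm).
#' @return An object of class `mechanical_state`: boundary radii, per-layer
#'   radius and stress profiles (`Trr`, `Tth`, `Tzz`, Lagrange multiplier
#'   `p`, fibre stress `tau`), the boundary residual and a `closed` flag.
#'   Convert with [as_tibble()] for plotting or export.
#' @export
solve_equilibrium <- function(geom, fields, k = 0, loads = load_case(),
                              mat = material_params(), r1_init = NULL,
                              closure_radius = 0.01, tol = 1e-12) {
  if (!is.list(k)) k <- agonist_field(geom, k)
  if (any(k$inner < 0) || any(k$outer < 0)) {
    abort_bad_arg("Agonist field must be non-negative.")
  }
  wts <- list(w_in = .quad_weights(geom$xi_in),
              w_out = .quad_weights(geom$xi_out))
  f <- function(r1) {
    .equilibrium_residual(r1, geom, fields, k, loads, mat, weights = wts)
  }

  lo_all <- 0.05 * xi1(geom)
  hi_all <- 3 * xi1(geom)

  bracket <- NULL
  if (!is.null(r1_init) && r1_init > lo_all && r1_init < hi_all) {
    # expand a small bracket around the warm start
    w <- 0.005 * xi1(geom)
    a <- max(lo_all, r1_init - w)
    b <- min(hi_all, r1_init + w)
    fa <- f(a); fb <- f(b)
    for (i in 1:40) {
      if (is.finite(fa) && is.finite(fb) && fa * fb <= 0) {
        bracket <- list(a = a, b = b, fa = fa, fb = fb)
        break
      }
      w <- 2 * w
      a <- max(lo_all, r1_init - w)
      b <- min(hi_all, r1_init + w)
      fa <- f(a); fb <- f(b)
      if (a == lo_all && b == hi_all) {
        if (fa * fb <= 0) bracket <- list(a = a, b = b, fa = fa, fb = fb)
        break
      }
    }
  }
  if (is.null(bracket)) {
    fa <- f(lo_all); fb <- f(hi_all)
    if (!is.finite(fa) || !is.finite(fb) || fa * fb > 0) {
      rlang::abort(
        sprintf(paste0(
          "Equilibrium shooting failed: residual does not change sign on ",
          "[%.4f, %.4f] mm (residuals %.4g, %.4g kPa)."),
          lo_all, hi_all, fa, fb),
        class = "airwaymorph_equilibrium_error"
      )
    }
    bracket <- list(a = lo_all, b = hi_all, fa = fa, fb = fb)
  }

  root <- stats::uniroot(f, c(bracket$a, bracket$b),
                         f.lower = bracket$fa, f.upper = bracket$fb,
                         tol = tol)
  r1 <- root$root

  prof <- .equilibrium_residual(r1, geom, fields, k, loads, mat,
                                profile = TRUE)
  ca <- cos(mat$alpha)^2
  sa <- sin(mat$alpha)^2
  finish_layer <- function(xi, r, Trr, d, phi, kk) {
    p <- d$hat$Trr_hat - Trr
    act <- phi$phi_c * active_force_density(kk, mat)
    Tth <- -p + d$hat$Tth_hat + act * ca
    Tzz <- -p + d$hat$Tzz_hat + act * sa
    list(xi = xi, r = r, Trr = Trr, Tth = Tth, Tzz = Tzz, p = p,
         tau = Tth * ca + Tzz * sa)
  }
  inner <- finish_layer(geom$xi_in, prof$r$r_in, prof$Trr_in, prof$d_in,
                        fields$inner, k$inner)
  outer <- finish_layer(geom$xi_out, prof$r$r_out, prof$Trr_out, prof$d_out,
                        fields$outer, k$outer)

  structure(
    list(r1 = r1, r_int = utils::tail(prof$r$r_in, 1),
         r2 = utils::tail(prof$r$r_out, 1),
         inner = inner, outer = outer,
         residual = prof$res, loads = loads,
         closed = r1 < closure_radius, converged = TRUE),
    class = "mechanical_state"
  )
}

#' @export
print.mechanical_state <- function(x, ...) {
  cat(sprintf(
    "<mechanical_state> r1 = %.4f, r2 = %.4f mm; residual %.2e kPa%s\n",
    x$r1, x$r2, x$residual, if (x$closed) " [CLOSED]" else ""
  ))
  invisible(x)
}

#' @export
as_tibble.mechanical_state <- function(x, ...) {
  grab <- function(l, layer) {
    tibble::tibble(layer = layer, xi = l$xi, r = l$r, Trr = l$Trr,
                   Tth = l$Tth, Tzz = l$Tzz, p = l$p, tau = l$tau)
  }
  dplyr::bind_rows(grab(x$inner, "inner"), grab(x$outer, "outer"))
}

#' Static pressure-radius curve
#'
#' One equilibrium solve per transmural pressure, warm-starting each solve
#' from the previous root. With no active tone the curve is monotone
#' non-decreasing; active contraction shifts it downwards.
#'
#' @inheritParams solve_equilibrium
#' @param pressures Sorted vector of luminal pressures P1 (kPa).
#' @param P2 External pressure (kPa).
#' @return A tibble of class `pr_curve` with columns
#'   `transmural_pressure_kPa`, `inner_radius_mm`, `converged`. Failed
#'   solves are recorded as `NA` with `converged = FALSE`.
#' @export
pressure_radius_curve <- function(geom, fields, k = 0,
                                  mat = material_params(), pressures,
                                  P2 = 0, ...) {
  if (any(!is.finite(pressures))) abort_bad_arg("`pressures` must be finite.")
  r1 <- rep(NA_real_, length(pressures))
  ok <- rep(FALSE, length(pressures))
  warm <- NULL
  for (i in seq_along(pressures)) {
    st <- tryCatch(
      solve_equilibrium(geom, fields, k, load_case(pressures[i], P2), mat,
                        r1_init = warm, ...),
      airwaymorph_equilibrium_error = function(e) NULL
    )
    if (!is.null(st)) {
      r1[i] <- st$r1
      ok[i] <- TRUE
      warm <- st$r1
    }
  }
  out <- tibble::tibble(
    transmural_pressure_kPa = pressures - P2,
    inner_radius_mm = r1,
    converged = ok
  )
  class(out) <- c("pr_curve", class(out))
  out
}
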