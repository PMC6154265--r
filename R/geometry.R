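#' Grown (stress-free) two-layer airway geometry
#'
#' Material grid of grown radii for the two-layer airway wall: an inner
#' collagen-only layer (the subepithelial basement membrane, SBM) between
#' the grown inner radius and the interface, and an outer, predominantly
#' smooth-muscle layer out to the fixed outer radius. Growth is purely
#' radial and inward: the outer grown radius is pinned at the reference
#' outer radius `R2` for all time, while interior material points move with
#' the growth velocity.
#'
#' The default reference radii (inner 1.8 mm, interface 1.95 mm, outer
#' 2.3 mm) describe a bovine-sized airway comparable to a generation-4
#' human airway, with an SBM thickness taken from airway histology.
#'
#' @param R1 Reference inner radius (mm).
#' @param R_int Reference interface radius (mm).
#' @param R2 Reference outer radius (mm).
#' @param n_inner,n_outer Number of material grid nodes per layer.
#' @param xi_in,xi_out Optional explicit grown-radius grids (mm); default is
#'   the ungrown state `xi = R`.
#' @return A list of class `grown_geometry` with per-layer grids `xi_in`,
#'   `xi_out` (the interface node is shared).
#' @export
grown_geometry <- function(R1 = 1.8, R_int = 1.95, R2 = 2.3,
                           n_inner = 101, n_outer = 101,
                           xi_in = NULL, xi_out = NULL) {
  check_number(R1, "R1", lower = 0, strict_lower = TRUE)
  check_number(R_int, "R_int", lower = R1, strict_lower = TRUE)
  check_number(R2, "R2", lower = R_int, strict_lower = TRUE)
  if (is.null(xi_in)) xi_in <- seq(R1, R_int, length.out = n_inner)
  if (is.null(xi_out)) xi_out <- seq(R_int, R2, length.out = n_outer)
  g <- structure(
    list(xi_in = xi_in, xi_out = xi_out, R1 = R1, R_int = R_int, R2 = R2),
    class = "grown_geometry"
  )
  validate_geometry(g)
  g
}

validate_geometry <- function(geom, tol = 1e-9) {
  if (any(diff(geom$xi_in) <= 0) || any(diff(geom$xi_out) <= 0)) {
    rlang::abort("Grown-radius grid is not strictly increasing (grid tangling).",
                 class = "airwaymorph_grid_error")
  }
  if (abs(utils::tail(geom$xi_in, 1) - geom$xi_out[1]) > tol) {
    rlang::abort("Layer grids do not conform at the interface.",
                 class = "airwaymorph_grid_error")
  }
  if (abs(utils::tail(geom$xi_out, 1) - geom$R2) > tol) {
    rlang::abort("Outer grown radius must stay pinned at R2.",
                 class = "airwaymorph_grid_error")
  }
  invisible(geom)
}

xi1 <- function(geom) geom$xi_in[1]
xi_int <- function(geom) geom$xi_out[1]
xi2 <- function(geom) utils::tail(geom$xi_out, 1)

#' @export
print.grown_geometry <- function(x, ...) {
  cat(sprintf(
    "<grown_geometry> xi1 = %.4f, xi_int = %.4f, xi2 = %.4f mm (%d + %d nodes)\n",
    xi1(x), xi_int(x), xi2(x), length(x$xi_in), length(x$xi_out)
  ))
  invisible(x)
}

#' @export
as_tibble.grown_geometry <- function(x, ...) {
  tibble::tibble(
    layer = c(rep("inner", length(x$xi_in)), rep("outer", length(x$xi_out))),
    xi = c(x$xi_in, x$xi_out)
  )
}

# fast path used by the equilibrium solver
.map_radii <- function(r1, geom) {
  a <- r1^2 - xi1(geom)^2
  list(r_in = sqrt(a + geom$xi_in^2), r_out = sqrt(a + geom$xi_out^2))
}

#' Incompressible mapping from grown to current radii
#'
#' For a trial current inner radius, maps every material node of the grown
#' configuration to its current radius via `r^2 = r1^2 + xi^2 - xi1^2`
#' (isochoric deformation of the annulus; continuity at the interface is
#' automatic, and annulus cross-sectional area is preserved exactly).
#'
#' @param r1 Trial current inner radius (mm, > 0).
#' @param geom A [grown_geometry()].
#' @return Tibble with columns `layer`, `xi`, `r`.
#' @export
map_radii <- function(r1, geom) {
  check_number(r1, "r1", lower = 0, strict_lower = TRUE)
  r <- .map_radii(r1, geom)
  out <- as_tibble(geom)
  out$r <- c(r$r_in, r$r_out)
  out
}

#' Constituent volume-fraction fields on the material grid
#'
#' Builds per-layer nodal volume fractions. By default the inner (SBM)
#' layer is pure ECM at the solid fraction and the outer layer takes the
#' supplied (scalar or nodal) values; pass `inner_ecm_only = FALSE` to put
#' the same mixture in both layers (used e.g. for homogeneous-tube
#' verification problems).
#'
#' @param geom A [grown_geometry()].
#' @param phi_c,phi_p,phi_e Outer-layer fractions; scalars are recycled
#'   across nodes.
#' @param phi_w Fluid fraction used to validate the solid-fraction sum.
#' @param inner_ecm_only If `TRUE` (default) the inner layer is
#'   `(0, 0, 1 - phi_w)`.
#' @return A list of class `constituent_fields` with per-layer components.
#' @export
constituent_fields <- function(geom, phi_c, phi_p, phi_e, phi_w = 0.7,
                               inner_ecm_only = TRUE) {
  n_in <- length(geom$xi_in)
  n_out <- length(geom$xi_out)
  expand <- function(x, n) if (length(x) == 1L) rep(x, n) else x
  outer <- list(phi_c = expand(phi_c, n_out), phi_p = expand(phi_p, n_out),
                phi_e = expand(phi_e, n_out))
  inner <- if (inner_ecm_only) {
    list(phi_c = rep(0, n_in), phi_p = rep(0, n_in),
         phi_e = rep(1 - phi_w, n_in))
  } else {
    list(phi_c = expand(phi_c, n_in), phi_p = expand(phi_p, n_in),
         phi_e = expand(phi_e, n_in))
  }
  f <- structure(list(inner = inner, outer = outer, phi_w = phi_w),
                 class = "constituent_fields")
  validate_fields(f)
  f
}

validate_fields <- function(fields, tol = 1e-8) {
  for (layer in c("inner", "outer")) {
    l <- fields[[layer]]
    .check_fractions(l$phi_c, l$phi_p, l$phi_e)
    s <- l$phi_c + l$phi_p + l$phi_e
    if (any(abs(s - (1 - fields$phi_w)) > tol)) {
      rlang::abort(sprintf(
        "Solid fractions in the %s layer do not sum to 1 - phi_w = %.3f.",
        layer, 1 - fields$phi_w
      ), class = "airwaymorph_input_error")
    }
  }
  invisible(fields)
}

#' Homeostatic fields on a geometry
#'
#' Convenience constructor: outer layer at the homeostatic steady state of
#' the turnover system, inner layer pure ECM.
#'
#' @param geom A [grown_geometry()].
#' @param rates A [rate_params()].
#' @return A `constituent_fields` object.
#' @export
homeostatic_fields <- function(geom, rates) {
  phi <- homeostatic_state(rates)
  constituent_fields(geom, phi[["phi_c"]], phi[["phi_p"]], phi[["phi_e"]],
                     phi_w = rates$phi_w)
}

#' @export
as_tibble.constituent_fields <- function(x, ...) {
  tibble::tibble(
    layer = c(rep("inner", length(x$inner$phi_c)),
              rep("outer", length(x$outer$phi_c))),
    phi_c = c(x$inner$phi_c, x$outer$phi_c),
    phi_p = c(x$inner$phi_p, x$outer$phi_p),
    phi_e = c(x$inner$phi_e, x$outer$phi_e)
  )
}

# agonist concentration field on the material grid
agonist_field <- function(geom, k = 0) {
  expand <- function(x, n) if (length(x) == 1L) rep(x, n) else x
  list(inner = expand(k, length(geom$xi_in)),
       outer = expand(k, length(geom$xi_out)))
}
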