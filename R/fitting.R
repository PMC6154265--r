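#' Generate a synthetic passive pressure-radius inflation table
#'
#' Forward-simulates the passive (agonist-free, ungrown, homeostatic)
#' pressure-radius curve and adds seeded Gaussian noise to the radii,
#' emulating quasi-static inflation data such as the bovine airway
#' measurements used to calibrate the passive response. The published
#' dataset is not bundled; this generator is the synthetic stand-in used
#' for parameter-recovery experiments.
#'
#' @param pressures Transmural pressures (kPa).
#' @param mat True [material_params()] generating the curve.
#' @param rates A [rate_params()] (fixes the homeostatic fractions).
#' @param geometry A [grown_geometry()].
#' @param noise_sd Noise standard deviation as a fraction of each radius
#'   (default 0.01 = 1%); `0` returns the exact forward curve.
#' @param seed Optional RNG seed (global RNG state is restored).
#' @return Tibble with `transmural_pressure_kPa`, `inner_radius_mm`;
#'   attribute `provenance = "synthetic"`.
#' @export
generate_synthetic_pr <- function(pressures,
                                  mat = material_params(),
                                  rates = rate_params(),
                                  geometry = grown_geometry(n_inner = 31,
                                                            n_outer = 31),
                                  noise_sd = 0.01, seed = NULL) {
  check_number(noise_sd, "noise_sd", lower = 0)
  fields <- homeostatic_fields(geometry, rates)
  curve <- pressure_radius_curve(geometry, fields, k = 0, mat = mat,
                                 pressures = pressures)
  r <- curve$inner_radius_mm
  if (noise_sd > 0) {
    eps <- with_seed(seed, rnorm(length(r), mean = 0, sd = noise_sd * r))
    r <- r + eps
  }
  out <- tibble::tibble(
    transmural_pressure_kPa = curve$transmural_pressure_kPa,
    inner_radius_mm = r
  )
  attr(out, "provenance") <- "synthetic"
  out
}

#' Fit passive material parameters to pressure-radius data
#'
#' Nonlinear least squares (Levenberg-Marquardt, with box constraints) of
#' the passive inflation model to quasi-static pressure-radius data, in the
#' ungrown reference geometry with homeostatic constituent fractions and no
#' agonist. By default the free coefficients are the two moduli the
#' inflation curve determines well: the shared ground-matrix stiffness
#' `c_ground` (low-pressure compliance) and the ECM collagen fibre modulus
#' `k1_e` (post-recruitment stiffening). The exponents, recruitment
#' stretch and fibre angle are held fixed (amplitude/shape trade-offs make
#' joint estimation sloppy), the proliferative-phase stiffness multiplies
#' a ~1% volume fraction and is structurally unidentifiable from inflation
#' data, and the active parameter `T_c` is never fitted (it is set
#' separately from active response data).
#'
#' @param data Data frame with columns `transmural_pressure_kPa` and
#'   `inner_radius_mm`.
#' @param free Character vector of [material_params()] fields to estimate.
#' @param start Named numeric starting values (default: the values in
#'   `mat`).
#' @param lower,upper Box constraints (named, recycled from defaults).
#' @param mat Fixed parameter values for everything not in `free`.
#' @param rates A [rate_params()].
#' @param geometry A [grown_geometry()].
#' @param control Passed to [minpack.lm::nls.lm.control()].
#' @return An object of class `pr_fit` with the estimates, fit object,
#'   fitted values, residuals and R-squared. Supports [tidy()], [glance()],
#'   [predict()] and [autoplot()].
#' @export
fit_passive_params <- function(data,
                               free = c("c_ground", "k1_e"),
                               start = NULL, lower = NULL, upper = NULL,
                               mat = material_params(),
                               rates = rate_params(),
                               geometry = grown_geometry(n_inner = 31,
                                                         n_outer = 31),
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 100)) {
  data <- tibble::as_tibble(data)
  need <- c("transmural_pressure_kPa", "inner_radius_mm")
  if (!all(need %in% names(data))) {
    abort_bad_arg(paste("`data` must have columns",
                        paste(need, collapse = ", ")))
  }
  if (!all(is.finite(data$transmural_pressure_kPa)) ||
      any(data$inner_radius_mm <= 0)) {
    abort_bad_arg("Pressures must be finite and radii positive.")
  }
  if (nrow(data) < length(free)) {
    abort_bad_arg("Need at least as many data points as free parameters.")
  }
  if (stats::sd(data$inner_radius_mm) < 1e-10) {
    rlang::abort("Degenerate data: radius is constant; fit is ill-posed.",
                 class = "airwaymorph_fit_error")
  }
  bad <- setdiff(free, names(mat))
  if (length(bad)) {
    abort_bad_arg(paste("Unknown material parameters:",
                        paste(bad, collapse = ", ")))
  }

  fields <- homeostatic_fields(geometry, rates)
  pressures <- data$transmural_pressure_kPa
  obs <- data$inner_radius_mm

  model_r1 <- function(par) {
    m <- mat
    m[free] <- as.list(par)
    pressure_radius_curve(geometry, fields, k = 0, mat = m,
                          pressures = pressures)$inner_radius_mm
  }
  resid_fn <- function(par) {
    pred <- model_r1(par)
    if (any(!is.finite(pred))) return(rep(1e3, length(obs)))
    obs - pred
  }

  p0 <- unlist(mat[free])
  if (!is.null(start)) p0[names(start)] <- start
  lo <- stats::setNames(rep(1e-8, length(free)), free)
  hi <- stats::setNames(rep(Inf, length(free)), free)
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper

  fit <- minpack.lm::nls.lm(par = p0, lower = lo, upper = hi,
                            fn = resid_fn, control = control)
  if (fit$info %in% c(0, 5)) {
    rlang::abort(
      sprintf("Passive fit did not converge: %s", fit$message),
      class = "airwaymorph_fit_error"
    )
  }
  est <- stats::setNames(as.numeric(fit$par), free)
  fitted <- model_r1(est)
  res <- obs - fitted
  ss_res <- sum(res^2)
  ss_tot <- sum((obs - mean(obs))^2)

  structure(
    list(estimate = est, fit = fit, free = free, mat = mat,
         data = data, fitted = fitted, residuals = res,
         r.squared = 1 - ss_res / ss_tot,
         sigma = sqrt(ss_res / max(1, length(obs) - length(free))),
         geometry = geometry, rates = rates),
    class = "pr_fit"
  )
}

#' @export
print.pr_fit <- function(x, ...) {
  cat("<pr_fit> passive pressure-radius fit\n")
  print(x$estimate)
  cat(sprintf("R-squared: %.6f (%d points, %d free parameters)\n",
              x$r.squared, nrow(x$data), length(x$free)))
  invisible(x)
}

#' Predict the fitted passive curve
#'
#' @param object A `pr_fit`.
#' @param pressures Transmural pressures (kPa); default: the data's.
#' @param ... Unused.
#' @return Tibble with `transmural_pressure_kPa`, `inner_radius_mm`.
#' @export
predict.pr_fit <- function(object, pressures = NULL, ...) {
  if (is.null(pressures)) pressures <- object$data$transmural_pressure_kPa
  m <- object$mat
  m[object$free] <- as.list(object$estimate)
  fields <- homeostatic_fields(object$geometry, object$rates)
  curve <- pressure_radius_curve(object$geometry, fields, k = 0, mat = m,
                                 pressures = pressures)
  tibble::tibble(transmural_pressure_kPa = curve$transmural_pressure_kPa,
                 inner_radius_mm = curve$inner_radius_mm)
}
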