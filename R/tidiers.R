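#' Tidy a simulation result
#'
#' Returns the stored time series as a tibble, one row per stored step.
#'
#' @param x An `airway_sim` result.
#' @param ... Unused.
#' @export
tidy.airway_sim <- function(x, ...) {
  x$series
}

#' One-row summary of a simulation
#'
#' Headline remodelling outcomes: remodelled (grown) and loaded inner
#' radii 5 days after the final challenge, agonist resolution time and
#' censoring, final wall thickness, and the closure/abort flags.
#'
#' @param x An `airway_sim` result.
#' @param ... Unused.
#' @export
glance.airway_sim <- function(x, ...) {
  rt <- agonist_resolution_time(x)
  tibble::tibble(
    remodelled_radius_mm = remodelled_inner_radius(x),
    loaded_radius_mm = remodelled_inner_radius(x, which = "loaded"),
    resolution_days = rt$resolution_days,
    censored = rt$censored,
    final_wall_thickness_mm = utils::tail(x$series$wall_thickness, 1),
    peak_mu = max(x$series$mu),
    closed = x$closed,
    aborted = x$aborted
  )
}

#' Tidy a passive pressure-radius fit
#'
#' Coefficient table in the broom convention.
#'
#' @param x A `pr_fit`.
#' @param ... Unused.
#' @export
tidy.pr_fit <- function(x, ...) {
  sm <- tryCatch(summary(x$fit), error = function(e) NULL)
  if (!is.null(sm)) {
    co <- stats::coef(sm)
    tibble::tibble(
      term = rownames(co),
      estimate = co[, "Estimate"],
      std.error = co[, "Std. Error"],
      statistic = co[, "t value"],
      p.value = co[, "Pr(>|t|)"]
    )
  } else {
    tibble::tibble(term = names(x$estimate), estimate = unname(x$estimate),
                   std.error = NA_real_, statistic = NA_real_,
                   p.value = NA_real_)
  }
}

#' One-row summary of a passive fit
#'
#' @param x A `pr_fit`.
#' @param ... Unused.
#' @export
glance.pr_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r.squared,
    sigma = x$sigma,
    nobs = nrow(x$data),
    n.par = length(x$free),
    niter = x$fit$niter,
    deviance = x$fit$deviance,
    converged = !(x$fit$info %in% c(0, 5))
  )
}
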