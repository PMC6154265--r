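#' Challenge protocol: a train of Gaussian stimulus events
#'
#' Allergen (inflammatory) or contractile-agonist challenges are modelled
#' as a train of Gaussian peaks
#' `f(t) = (2 pi sigma^2)^(-1/2) sum_i exp(-d (t - t_i)^2 / (2 sigma^2))`,
#' confined to a challenge window at the start of a much longer simulation
#' horizon so that post-challenge resolution can be studied. With `d = 1`
#' each peak integrates to one.
#'
#' Event times may be given explicitly or generated periodically from a
#' frequency `omega` (events 1/omega days apart starting at `t_start`).
#'
#' @param event_times Optional explicit event days.
#' @param omega Challenge frequency (1/day), used when `event_times` is
#'   `NULL`.
#' @param t_start Day of the first periodic event.
#' @param sigma Peak width (days).
#' @param d Dimensionless shape constant (default 1).
#' @param challenge_window Events must lie within `[0, challenge_window]`
#'   days.
#' @param horizon Total simulated duration (days).
#' @return A list of class `challenge_protocol`.
#' @export
challenge_protocol <- function(event_times = NULL, omega = 0.5, t_start = 1,
                               sigma = 0.5, d = 1,
                               challenge_window = 50, horizon = 1000) {
  check_number(sigma, "sigma", lower = 0, strict_lower = TRUE)
  check_number(d, "d", lower = 0, strict_lower = TRUE)
  check_number(challenge_window, "challenge_window", lower = 0)
  check_number(horizon, "horizon", lower = challenge_window)
  if (is.null(event_times)) {
    check_number(omega, "omega", lower = 0, strict_lower = TRUE)
    event_times <- seq(t_start, challenge_window, by = 1 / omega)
  }
  event_times <- as.numeric(event_times)
  if (is.unsorted(event_times)) {
    abort_bad_arg("`event_times` must be sorted.")
  }
  if (length(event_times) &&
      (min(event_times) < 0 || max(event_times) > challenge_window)) {
    abort_bad_arg("`event_times` must lie within the challenge window.")
  }
  structure(
    list(event_times = event_times, sigma = sigma, d = d,
         challenge_window = challenge_window, horizon = horizon),
    class = "challenge_protocol"
  )
}

#' @export
print.challenge_protocol <- function(x, ...) {
  cat(sprintf(
    "<challenge_protocol> %d events in [0, %g] d, sigma = %g d, horizon %g d\n",
    length(x$event_times), x$challenge_window, x$sigma, x$horizon
  ))
  invisible(x)
}

#' Evaluate the challenge event train
#'
#' @param t Time(s) in days.
#' @param proto A [challenge_protocol()].
#' @return `f(t)` (1/day), non-negative, vectorised over `t`.
#' @export
challenge_train <- function(t, proto) {
  if (length(proto$event_times) == 0L) return(rep(0, length(t)))
  amp <- 1 / sqrt(2 * pi * proto$sigma^2)
  dev2 <- outer(t, proto$event_times, function(a, b) (a - b)^2)
  amp * rowSums(exp(-proto$d * dev2 / (2 * proto$sigma^2)))
}

#' Advance the global inflammatory status
#'
#' One step of `dmu/dt = a_mu f(t) - c_dmu mu`, using the exact exponential
#' decay factor with trapezoidal treatment of the forcing, so pure decay is
#' integrated exactly and `mu` can never go negative.
#'
#' @param mu Current inflammatory status.
#' @param t Current time (days); the step advances to `t + dt`.
#' @param dt Step size (days, > 0).
#' @param proto A [challenge_protocol()].
#' @param stim A [stimulus_params()].
#' @return Updated `mu`.
#' @export
step_inflammation <- function(mu, t, dt, proto, stim) {
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  dec <- exp(-stim$c_dmu * dt)
  f0 <- challenge_train(t, proto)
  f1 <- challenge_train(t + dt, proto)
  mu * dec + stim$a_mu * dt / 2 * (f0 * dec + f1)
}

#' Advance the local agonist concentration field
#'
#' One step of `dk/dt = a_k f(t) - c_dk k + a_kmu mu + a_c tau H(tau)` on
#' every material node. Only tensile fibre stress releases agonist
#' (`H(tau) = 0` for `tau <= 0`). The agonist rides the Lagrangian material
#' grid (no diffusion). Exact decay factor, trapezoidal forcing; any
#' negative undershoot is clipped to zero with a warning.
#'
#' @param k Nodal agonist concentrations (numeric vector).
#' @param tau Nodal fibre-direction stress (kPa), from the current
#'   equilibrium solve.
#' @param mu Inflammatory status at the start of the step.
#' @param t Current time (days).
#' @param dt Step size (days, > 0).
#' @param proto A [challenge_protocol()].
#' @param stim A [stimulus_params()].
#' @param mu_next Inflammatory status at `t + dt` (defaults to `mu`).
#' @return Updated nodal `k`, non-negative.
#' @export
step_agonist <- function(k, tau, mu, t, dt, proto, stim, mu_next = mu) {
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  dec <- exp(-stim$c_dk * dt)
  rel <- stim$a_c * ppart(tau) # strictly tensile trigger, held over the step
  u0 <- stim$a_k * challenge_train(t, proto) + stim$a_kmu * mu + rel
  u1 <- stim$a_k * challenge_train(t + dt, proto) + stim$a_kmu * mu_next + rel
  out <- k * dec + dt / 2 * (u0 * dec + u1)
  if (any(out < 0)) {
    rlang::warn("Agonist step undershot zero; clipping to 0.")
    out <- pmax(out, 0)
  }
  out
}

#' Total agonist in the airway cross-section
#'
#' Integral of the agonist field over the grown cross-section, used to
#' define the resolution time (the series crossing below 1e-6 after the
#' final challenge). The default measure is area-weighted,
#' `int k(xi) 2 pi xi dxi` over both layers of the grown annulus; a plain
#' radial integral is also available. Piecewise-parabolic quadrature, exact
#' for nodally linear agonist fields under the area weight.
#'
#' @param k Agonist field (scalar or per-layer list).
#' @param geom A [grown_geometry()].
#' @param weighting `"area"` (default) or `"radial"`.
#' @return A single non-negative number.
#' @export
total_agonist <- function(k, geom, weighting = c("area", "radial")) {
  weighting <- match.arg(weighting)
  if (!is.list(k)) k <- agonist_field(geom, k)
  w_in <- if (weighting == "area") 2 * pi * geom$xi_in else rep(1, length(geom$xi_in))
  w_out <- if (weighting == "area") 2 * pi * geom$xi_out else rep(1, length(geom$xi_out))
  sum(.quad_weights(geom$xi_in) * k$inner * w_in) +
    sum(.quad_weights(geom$xi_out) * k$outer * w_out)
}
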