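#' Full simulation configuration
#'
#' Bundles geometry, material, rate and stimulus parameters, the challenge
#' protocol, loads, numerical settings and mode flags into one validated
#' object. The challenge mode zeroes the unused channel at run time:
#' `"inflammation"` sets `a_k = 0` (allergen challenges only),
#' `"agonist"` sets `a_mu = 0` (methacholine-style challenges only),
#' `"combined"` keeps both.
#'
#' @param geometry A [grown_geometry()] (reference = ungrown state).
#' @param material A [material_params()].
#' @param rates A [rate_params()].
#' @param stimuli A [stimulus_params()].
#' @param protocol A [challenge_protocol()].
#' @param loads A [load_case()] held fixed during growth.
#' @param mode Challenge mode, see Details.
#' @param sbm_thickening If `TRUE`, inflammation-driven ECM turnover also
#'   operates in the inner (SBM) layer, with the outer-layer deposition and
#'   degradation rates.
#' @param dt Growth time step (days).
#' @param closure_radius Lumen radius (mm) below which the airway is
#'   flagged closed and the run stops.
#' @param snapshot_days Days at which full transmural snapshots are stored.
#' @param store_every Store a series row every `store_every` steps.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(geometry = grown_geometry(),
                              material = material_params(),
                              rates = rate_params(),
                              stimuli = stimulus_params(),
                              protocol = challenge_protocol(),
                              loads = load_case(),
                              mode = c("inflammation", "agonist", "combined"),
                              sbm_thickening = FALSE,
                              dt = 0.05,
                              closure_radius = 0.01,
                              snapshot_days = numeric(0),
                              store_every = 1L) {
  mode <- match.arg(mode)
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  check_number(closure_radius, "closure_radius", lower = 0)
  stopifnot(inherits(geometry, "grown_geometry"),
            inherits(material, "material_params"),
            inherits(rates, "rate_params"),
            inherits(stimuli, "stimulus_params"),
            inherits(protocol, "challenge_protocol"),
            inherits(loads, "load_case"))
  structure(
    list(geometry = geometry, material = material, rates = rates,
         stimuli = stimuli, protocol = protocol, loads = loads,
         mode = mode, sbm_thickening = sbm_thickening, dt = dt,
         closure_radius = closure_radius,
         snapshot_days = as.numeric(snapshot_days),
         store_every = as.integer(store_every)),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "<simulation_config> mode = %s, horizon = %g d, dt = %g d, %d challenges\n",
    x$mode, x$protocol$horizon, x$dt, length(x$protocol$event_times)
  ))
  invisible(x)
}

# effective stimulus parameters after applying the challenge mode
.effective_stimuli <- function(cfg) {
  stim <- cfg$stimuli
  if (cfg$mode == "inflammation") stim$a_k <- 0
  if (cfg$mode == "agonist") stim$a_mu <- 0
  stim
}

#' Run a coupled growth-mechanics simulation
#'
#' Operator-split time stepping over the full horizon. Each step, in order:
#' (1) advance the global inflammatory status; (2) solve quasi-static
#' elastic equilibrium on the current grown geometry with the current
#' constituent and agonist fields, yielding the fibre-direction stress
#' profile; (3) advance the agonist field (challenges, inflammation-induced
#' and tensile-stress-induced release, clearance); (4) evaluate source
#' terms, dilatation and growth velocity and advance the volume fractions
#' and grown radii. The run is deterministic given the configuration.
#'
#' The run stops early, with the `closed` flag set, if the loaded inner
#' radius drops below the closure threshold; an equilibrium failure or grid
#' tangling aborts with partial output and a diagnostic.
#'
#' @param cfg A [simulation_config()].
#' @param quiet Suppress progress messages.
#' @return An object of class `airway_sim`: `series` (one row per stored
#'   step: time, inflammation, total agonist, loaded and grown inner radii,
#'   wall thickness, mean outer-layer fractions, stress extremes),
#'   `snapshots` (transmural profiles at requested days), flags `closed`
#'   and `aborted`, and the configuration. Use [tidy()], [glance()],
#'   [autoplot()], [remodelled_inner_radius()] and
#'   [agonist_resolution_time()] on the result.
#' @export
run_simulation <- function(cfg, quiet = TRUE) {
  stopifnot(inherits(cfg, "simulation_config"))
  stim <- .effective_stimuli(cfg)
  proto <- cfg$protocol
  rates <- cfg$rates
  mat <- cfg$material
  geom <- cfg$geometry
  fields <- homeostatic_fields(geom, rates)
  k <- agonist_field(geom, 0)
  mu <- 0

  n_steps <- ceiling(proto$horizon / cfg$dt)
  n_keep <- floor(n_steps / cfg$store_every) + 1L
  series <- matrix(NA_real_, nrow = n_keep, ncol = 12L)
  colnames(series) <- c("t", "mu", "k_total", "k_max", "r1_loaded", "xi1",
                        "xi_int", "wall_thickness", "phi_c_mean",
                        "phi_p_mean", "phi_e_mean", "tau_max")
  snap_days <- sort(unique(cfg$snapshot_days))
  snaps <- vector("list", length(snap_days))
  snap_taken <- rep(FALSE, length(snap_days))

  mech <- solve_equilibrium(geom, fields, k, cfg$loads, mat,
                            closure_radius = cfg$closure_radius)
  closed <- FALSE
  aborted <- FALSE
  diagnostic <- NULL
  row <- 0L

  record <- function(i_step, t) {
    tot_k <- total_agonist(k, geom)
    c(t, mu, tot_k, max(k$inner, k$outer),
      mech$r1, xi1(geom), xi_int(geom), xi2(geom) - xi1(geom),
      mean(fields$outer$phi_c), mean(fields$outer$phi_p),
      mean(fields$outer$phi_e), max(mech$inner$tau, mech$outer$tau))
  }
  maybe_snapshot <- function(t) {
    for (j in seq_along(snap_days)) {
      if (!snap_taken[j] && t >= snap_days[j] - cfg$dt / 2) {
        tb <- as_tibble(mech)
        tb$day <- snap_days[j]
        tb$phi_c <- c(fields$inner$phi_c, fields$outer$phi_c)
        tb$phi_p <- c(fields$inner$phi_p, fields$outer$phi_p)
        tb$phi_e <- c(fields$inner$phi_e, fields$outer$phi_e)
        tb$k <- c(k$inner, k$outer)
        snaps[[j]] <<- tb
        snap_taken[j] <<- TRUE
      }
    }
  }

  row <- row + 1L
  series[row, ] <- record(0L, 0)
  maybe_snapshot(0)

  t <- 0
  for (i in seq_len(n_steps)) {
    mu_new <- step_inflammation(mu, t, cfg$dt, proto, stim)
    mech_try <- tryCatch(
      solve_equilibrium(geom, fields, k, cfg$loads, mat,
                        r1_init = mech$r1,
                        closure_radius = cfg$closure_radius),
      airwaymorph_equilibrium_error = function(e) e
    )
    if (inherits(mech_try, "condition")) {
      aborted <- TRUE
      diagnostic <- conditionMessage(mech_try)
      break
    }
    mech <- mech_try
    tau <- list(inner = mech$inner$tau, outer = mech$outer$tau)
    k$inner <- step_agonist(k$inner, tau$inner, mu, t, cfg$dt, proto, stim,
                            mu_next = mu_new)
    k$outer <- step_agonist(k$outer, tau$outer, mu, t, cfg$dt, proto, stim,
                            mu_next = mu_new)
    mu <- mu_new

    s_out <- .source_terms(fields$outer$phi_c, fields$outer$phi_p,
                           fields$outer$phi_e, mu, tau$outer, rates)
    n_in <- length(geom$xi_in)
    if (cfg$sbm_thickening) {
      # inner layer: ECM turnover only, same deposition/degradation rates
      s_in <- list(
        S_c = rep(0, n_in), S_p = rep(0, n_in),
        S_e = ecm_deposition_rate(mu, rates) / rates$rho_T -
          rates$c_de * fields$inner$phi_e
      )
    } else {
      s_in <- list(S_c = rep(0, n_in), S_p = rep(0, n_in), S_e = rep(0, n_in))
    }
    q <- list(
      inner = mixture_dilatation(s_in$S_c, s_in$S_p, s_in$S_e, rates),
      outer = mixture_dilatation(s_out$S_c, s_out$S_p, s_out$S_e, rates)
    )
    v <- growth_velocity(q, geom)
    # inward growth velocity diverges as the lumen vanishes; stop before
    # the grid can cross zero
    if (xi1(geom) + cfg$dt * v$inner[1] < cfg$closure_radius) {
      closed <- TRUE
      break
    }
    adv <- tryCatch(
      advance_growth(fields, geom, list(inner = s_in, outer = s_out),
                     q, v, cfg$dt),
      airwaymorph_grid_error = function(e) e
    )
    if (inherits(adv, "condition")) {
      aborted <- TRUE
      diagnostic <- conditionMessage(adv)
      break
    }
    fields <- adv$fields
    geom <- adv$geom
    t <- i * cfg$dt

    if (i %% cfg$store_every == 0L) {
      row <- row + 1L
      series[row, ] <- record(i, t)
    }
    maybe_snapshot(t)

    if (mech$closed || xi1(geom) < cfg$closure_radius) {
      closed <- TRUE
      break
    }
    if (!quiet && i %% 2000L == 0L) {
      message(sprintf("day %.1f: r1 = %.4f mm, mu = %.3f", t, mech$r1, mu))
    }
  }

  series <- tibble::as_tibble(series[seq_len(row), , drop = FALSE])
  snapshots <- dplyr::bind_rows(snaps[snap_taken])
  structure(
    list(series = series, snapshots = snapshots,
         closed = closed, aborted = aborted, diagnostic = diagnostic,
         final_geom = geom, final_fields = fields, final_k = k,
         config = cfg,
         last_event_time = if (length(proto$event_times))
           max(proto$event_times) else 0),
    class = "airway_sim"
  )
}

#' @export
print.airway_sim <- function(x, ...) {
  cat(sprintf(
    "<airway_sim> %d stored steps to day %.1f; xi1 = %.4f mm%s%s\n",
    nrow(x$series), max(x$series$t), utils::tail(x$series$xi1, 1),
    if (x$closed) " [CLOSED]" else "",
    if (x$aborted) " [ABORTED]" else ""
  ))
  invisible(x)
}

#' Remodelled inner radius
#'
#' Inner radius a fixed number of days after the final challenge, the
#' headline remodelling outcome. Reported by default in the grown
#' (unloaded, agonist-free) configuration, i.e. the grown radius `xi1`;
#' the loaded radius is available via `which = "loaded"`. Linearly
#' interpolated on the stored series.
#'
#' @param result An `airway_sim` result.
#' @param days_after Days after the final challenge (default 5).
#' @param which `"grown"` or `"loaded"`.
#' @return Radius in mm (`NA` if the series ends before the query time).
#' @export
remodelled_inner_radius <- function(result, days_after = 5,
                                    which = c("grown", "loaded")) {
  which <- match.arg(which)
  t_query <- result$last_event_time + days_after
  col <- if (which == "grown") "xi1" else "r1_loaded"
  s <- result$series
  if (t_query > max(s$t)) return(NA_real_)
  stats::approx(s$t, s[[col]], xout = t_query)$y
}

#' Agonist resolution time
#'
#' Days between the final challenge and the decay of the cross-sectional
#' agonist total below a threshold (default 1e-6). The crossing is located
#' by log-linear interpolation between stored samples (exact for
#' exponential decay). Runs whose agonist never resolves within the
#' horizon are censored, never assigned a number.
#'
#' @param result An `airway_sim` result, or a data frame with columns `t`
#'   and `k_total` (then supply `t_last`).
#' @param threshold Resolution threshold on the cross-sectional total.
#' @param t_last Final challenge time, required for data-frame input.
#' @return One-row tibble with `resolution_days` (`NA` when censored) and
#'   `censored`.
#' @export
agonist_resolution_time <- function(result, threshold = 1e-6, t_last = NULL) {
  if (inherits(result, "airway_sim")) {
    s <- result$series
    t_last <- result$last_event_time
  } else {
    s <- tibble::as_tibble(result)
    if (is.null(t_last)) abort_bad_arg("Supply `t_last` for data-frame input.")
  }
  s <- s[s$t >= t_last, c("t", "k_total")]
  if (nrow(s) == 0L) {
    return(tibble::tibble(resolution_days = NA_real_, censored = TRUE))
  }
  below <- s$k_total < threshold
  if (!any(below)) {
    return(tibble::tibble(resolution_days = NA_real_, censored = TRUE))
  }
  i <- which(below)[1]
  if (i == 1L) {
    return(tibble::tibble(resolution_days = s$t[1] - t_last, censored = FALSE))
  }
  t0 <- s$t[i - 1L]; t1 <- s$t[i]
  y0 <- s$k_total[i - 1L]; y1 <- s$k_total[i]
  t_cross <- if (y0 > 0 && y1 > 0) {
    t0 + (t1 - t0) * (log(y0) - log(threshold)) / (log(y0) - log(y1))
  } else {
    t0 + (t1 - t0) * (y0 - threshold) / (y0 - y1)
  }
  tibble::tibble(resolution_days = t_cross - t_last, censored = FALSE)
}

#' Set a named parameter anywhere in a simulation configuration
#'
#' Resolves a bare parameter name (`"c_dmu"`, `"T_c"`, `"c_dk"`, ...) to
#' its block in the configuration (stimuli, rates, material or protocol)
#' and returns an updated copy; this is how sweep axes address parameters.
#' The pseudo-names `"omega"`, `"omega_mu"` and `"omega_k"` rebuild the
#' periodic challenge train at the given frequency. Ambiguous or unknown
#' names fail.
#'
#' @param cfg A [simulation_config()].
#' @param name Parameter name.
#' @param value New value.
#' @return The updated configuration.
#' @export
set_config_param <- function(cfg, name, value) {
  if (name %in% c("omega", "omega_mu", "omega_k")) {
    p <- cfg$protocol
    cfg$protocol <- challenge_protocol(
      omega = value, t_start = min(p$event_times %||% 1),
      sigma = p$sigma, d = p$d,
      challenge_window = p$challenge_window, horizon = p$horizon
    )
    return(cfg)
  }
  blocks <- c("stimuli", "rates", "material", "protocol")
  hit <- blocks[vapply(blocks, function(b) name %in% names(cfg[[b]]),
                       logical(1))]
  if (length(hit) == 0L && name %in% names(cfg)) {
    cfg[[name]] <- value
    return(cfg)
  }
  if (length(hit) != 1L) {
    abort_bad_arg(sprintf(
      "Parameter `%s` does not resolve to a unique configuration entry.", name
    ))
  }
  cfg[[hit]][[name]] <- value
  cfg
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Two-parameter sweep experiment
#'
#' Runs an independent simulation for every combination of two parameter
#' grids (results do not depend on execution order) and collects the
#' remodelling outcome surface: remodelled inner radius, agonist resolution
#' time and closure mask. Closed runs are masked (`NA` outcomes), matching
#' the convention of discarding parameter choices that drive the airway
#' into the lumen. Axis names resolve into the stimulus, rate, material or
#' protocol blocks; `"omega"`/`"omega_mu"`/`"omega_k"` rebuild the periodic
#' challenge train.
#'
#' @param cfg Base [simulation_config()].
#' @param axis1,axis2 Lists `list(name = , values = )`.
#' @param days_after Passed to [remodelled_inner_radius()].
#' @param quiet Suppress per-run progress.
#' @return Tibble of class `airway_sweep`: one row per grid point with the
#'   axis values, `remodelled_radius_mm`, `resolution_days`, `censored`,
#'   `closed`, `aborted`.
#' @export
parameter_sweep <- function(cfg, axis1, axis2, days_after = 5,
                            quiet = TRUE) {
  grid <- tidyr::expand_grid(a1 = axis1$values, a2 = axis2$values)
  res <- purrr::pmap(grid, function(a1, a2) {
    cfg_i <- set_config_param(cfg, axis1$name, a1)
    cfg_i <- set_config_param(cfg_i, axis2$name, a2)
    sim <- run_simulation(cfg_i, quiet = TRUE)
    rt <- agonist_resolution_time(sim)
    tibble::tibble(
      remodelled_radius_mm =
        if (sim$closed) NA_real_ else remodelled_inner_radius(sim, days_after),
      resolution_days = if (sim$closed) NA_real_ else rt$resolution_days,
      censored = rt$censored,
      closed = sim$closed,
      aborted = sim$aborted
    )
  })
  out <- dplyr::bind_cols(
    stats::setNames(grid, c(axis1$name, axis2$name)),
    dplyr::bind_rows(res)
  )
  attr(out, "axes") <- c(axis1$name, axis2$name)
  class(out) <- c("airway_sweep", class(out))
  out
}
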