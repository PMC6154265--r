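test_that("switching, proliferation and deposition rates follow the tiers", {
  rates <- rate_params()
  expect_equal(switching_rate(0, 0, rates), rates$c_c0)
  expect_equal(switching_rate(1, 0, rates), rates$c_c1) # mild tier
  expect_equal(switching_rate(10, 0, rates), rates$c_c2) # severe tier
  # thresholds act strictly: at exactly mu_1 the rate is still baseline
  expect_equal(switching_rate(rates$mu_1, 0, rates), rates$c_c0)
  expect_equal(switching_rate(0, 2, rates), rates$c_c0 + 2 * rates$c_cp_f)
  expect_equal(switching_rate(0, -2, rates), rates$c_c0) # tension mode

  comp <- rate_params(switch_mode = "compression", c_p_f = 0.05,
                      prolif_mode = "compression")
  # compressive mode uses the stress magnitude, so the increment is positive
  expect_equal(switching_rate(0, -2, comp), comp$c_c0 + 2 * comp$c_cp_f)
  expect_equal(switching_rate(0, 2, comp), comp$c_c0)
  expect_equal(proliferation_rate(-1, comp), comp$c_p0 + 0.05)
  expect_equal(proliferation_rate(1, comp), comp$c_p0)

  tens <- rate_params(c_p_f = 0.05)
  expect_equal(proliferation_rate(0, tens), tens$c_p0)
  expect_equal(proliferation_rate(-3, tens), tens$c_p0)
  expect_equal(proliferation_rate(3, tens), tens$c_p0 + 0.15)

  expect_equal(ecm_deposition_rate(0, rates), rates$c_e0)
  expect_equal(ecm_deposition_rate(1, rates), rates$c_e1)
  expect_equal(ecm_deposition_rate(99, rates), rates$c_e2)
  expect_equal(ecm_deposition_rate(rates$mu_2, rates), rates$c_e1)
})

test_that("source terms vanish at homeostasis and match the density-form oracle", {
  rates <- rate_params()
  phi <- homeostatic_state(rates)
  hs <- source_terms(tibble::tibble(phi_c = phi[1], phi_p = phi[2],
                                    phi_e = phi[3], tau = 0),
                     mu = 0, rates = rates)
  expect_lt(max(abs(c(hs$S_c, hs$S_p, hs$S_e))), 1e-15)

  set.seed(7)
  for (i in 1:25) {
    f <- tibble::tibble(phi_c = runif(1, 0, 0.3), phi_p = runif(1, 0, 0.3),
                        phi_e = runif(1, 0, 0.3), tau = runif(1, -3, 3))
    mu <- runif(1, 0, 3)
    got <- source_terms(f, mu, rates)
    want <- oracle_sources(f$phi_c, f$phi_p, f$phi_e, mu, f$tau, rates)
    expect_equal(got$S_c, want$S_c, tolerance = 1e-12)
    expect_equal(got$S_p, want$S_p, tolerance = 1e-12)
    expect_equal(got$S_e, want$S_e, tolerance = 1e-12)
  }

  # severe inflammation seeds the proliferative pool from contractile cells
  seed <- source_terms(tibble::tibble(phi_c = 0.2, phi_p = 0, phi_e = 0.1,
                                      tau = 0), mu = 10, rates = rates)
  expect_gt(seed$S_p, 0)
})

test_that("closed-form homeostatic state agrees with an independent ODE solve", {
  skip_if_not_installed("deSolve")
  rates <- rate_params()
  phi <- homeostatic_state(rates)
  expect_equal(sum(phi), 0.3, tolerance = 1e-12)

  rhs <- function(t, y, parms) list(wellmixed_rhs(y, rates))
  start <- phi * c(1.4, 0.5, 1.1)
  start <- start / sum(start) * 0.3
  sol <- deSolve::lsoda(y = unname(start), times = c(0, 3000), func = rhs,
                        rtol = 1e-11, atol = 1e-12)
  expect_equal(unname(sol[2, 2:4]), unname(phi), tolerance = 1e-6)
})

test_that("homeostatic state is linearly stable and needs c_pc > c_p0", {
  rates <- rate_params()
  phi <- homeostatic_state(rates)
  h <- 1e-7
  # the solid-fraction sum is a conserved structure of the flow (neutral
  # direction); stability is assessed within the constraint manifold,
  # parametrised by (phi_c, phi_p) with phi_e dependent
  red <- function(cp) {
    full <- wellmixed_rhs(c(cp[1], cp[2], 0.3 - cp[1] - cp[2]), rates)
    full[1:2]
  }
  J <- matrix(0, 2, 2)
  for (j in 1:2) {
    e <- numeric(2); e[j] <- h
    J[, j] <- (red(phi[1:2] + e) - red(phi[1:2] - e)) / (2 * h)
  }
  expect_lt(max(Re(eigen(J, only.values = TRUE)$values)), 0)
  # the full 3x3 Jacobian adds only the neutral sum direction
  J3 <- matrix(0, 3, 3)
  for (j in 1:3) {
    e <- numeric(3); e[j] <- h
    J3[, j] <- (wellmixed_rhs(phi + e, rates) -
                  wellmixed_rhs(phi - e, rates)) / (2 * h)
  }
  expect_lt(max(Re(eigen(J3, only.values = TRUE)$values)), 1e-6)

  bad <- rates
  bad$c_pc <- 0.05 # below c_p0
  expect_error(homeostatic_state(bad),
               class = "airwaymorph_steady_state_error")
  expect_error(rate_params(c_pc = 0.05, c_p0 = 0.1),
               class = "airwaymorph_steady_state_error")
})

test_that("mixture dilatation converts net solid production to volume growth", {
  rates <- rate_params()
  expect_identical(mixture_dilatation(0, 0, 0, rates), 0)
  expect_equal(mixture_dilatation(0.01, 0.01, 0.01, rates), 0.1,
               tolerance = 1e-14)
  set.seed(11)
  s <- matrix(rnorm(30), 10, 3)
  expect_equal(mixture_dilatation(s[, 1], s[, 2], s[, 3], rates),
               rowSums(s) / 0.3, tolerance = 1e-13)
})

test_that("growth velocity integrates inward from the pinned outer wall", {
  geom <- small_geom(41)
  v0 <- growth_velocity(0, geom)
  expect_identical(v0$inner, rep(0, 41))
  expect_identical(v0$outer, rep(0, 41))

  # uniform dilatation in the outer layer only: closed-form interface speed
  q0 <- 0.2
  q <- list(inner = rep(0, 41), outer = rep(q0, 41))
  v <- growth_velocity(q, geom)
  xi_i <- geom$xi_out[1]
  expect_equal(v$outer[1], -q0 * (2.3^2 - xi_i^2) / (2 * xi_i),
               tolerance = 1e-12)
  expect_equal(tail(v$outer, 1), 0)
  expect_true(all(v$inner < 0)) # everything below the growth moves inward
  expect_equal(v$inner[41], v$outer[1], tolerance = 1e-14) # continuity
})

test_that("growth update preserves the solid fraction and thickens inward", {
  geom <- small_geom(21)
  rates <- rate_params()
  fields <- homeostatic_fields(geom, rates)

  # at the fixed point nothing moves
  zero <- list(S_c = rep(0, 21), S_p = rep(0, 21), S_e = rep(0, 21))
  q0 <- list(inner = rep(0, 21), outer = rep(0, 21))
  adv <- advance_growth(fields, geom, list(inner = zero, outer = zero),
                        q0, growth_velocity(q0, geom), dt = 0.5)
  expect_identical(adv$geom$xi_in, geom$xi_in)
  expect_identical(adv$fields$outer$phi_c, fields$outer$phi_c)

  # net production in the outer layer: inner radius shrinks, outer pinned,
  # solid-fraction sum exactly maintained by the update
  S <- list(S_c = rep(0.01, 21), S_p = rep(0.01, 21), S_e = rep(0.01, 21))
  q <- list(inner = rep(0, 21),
            outer = mixture_dilatation(S$S_c, S$S_p, S$S_e, rates))
  adv2 <- advance_growth(fields, geom, list(inner = zero, outer = S), q,
                         growth_velocity(q, geom), dt = 0.5)
  expect_lt(adv2$geom$xi_in[1], geom$xi_in[1])
  expect_equal(tail(adv2$geom$xi_out, 1), 2.3)
  sums <- adv2$fields$outer$phi_c + adv2$fields$outer$phi_p +
    adv2$fields$outer$phi_e
  expect_equal(sums, rep(0.3, 21), tolerance = 1e-14)

  # a non-monotone updated grid aborts
  v_bad <- list(inner = c(1, rep(0, 20)), outer = rep(0, 21))
  expect_error(
    advance_growth(fields, geom, list(inner = zero, outer = zero),
                   q0, v_bad, dt = 1),
    class = "airwaymorph_grid_error"
  )
})

test_that("day-55 remodelling is converged in step and grid resolution", {
  run <- function(dt, n) {
    cfg <- simulation_config(
      geometry = grown_geometry(n_inner = n, n_outer = n),
      protocol = challenge_protocol(horizon = 55),
      dt = dt, store_every = 10L
    )
    remodelled_inner_radius(run_simulation(cfg), days_after = 5)
  }
  coarse <- run(0.05, 41)
  fine <- run(0.025, 81)
  expect_lt(abs(fine - coarse) / fine, 0.005)
})
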