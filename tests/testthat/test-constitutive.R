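test_that("Hill active force density matches closed form and saturates", {
  mat <- material_params(T_c = 2, K_d = 1, n_hill = 2)
  expect_identical(active_force_density(0, mat), 0)
  # half-saturation where k^n = K_d, by construction
  expect_equal(active_force_density(1, mat), 1)
  expect_equal(active_force_density(3, mat), 2 * 9 / 10)

  mat2 <- material_params(T_c = 7, K_d = 0.3, n_hill = 1.5)
  expect_equal(active_force_density(0.3^(1 / 1.5), mat2), 3.5)
  k <- seq(0, 50, length.out = 400)
  a <- active_force_density(k, mat2)
  expect_true(all(diff(a) > 0))
  expect_true(all(a < 7))
  expect_equal(active_force_density(1e8, mat2), 7, tolerance = 1e-8)

  expect_error(active_force_density(-0.1, mat),
               class = "airwaymorph_input_error")
})

test_that("unstrained reference is exactly stress-free", {
  mat <- material_params()
  pts <- tibble::tibble(lam_r = 1, lam_th = 1, lam_z = 1,
                        phi_c = 0.12, phi_p = 0.01, phi_e = 0.17, k = 0)
  out <- total_stress(pts, mat)
  expect_identical(out$Trr_hat, 0)
  expect_identical(out$Tth_hat, 0)
  expect_identical(out$Tzz_hat, 0)
  expect_identical(out$Trr, 0)
  expect_identical(out$Tth, 0)
  expect_identical(out$Tzz, 0)
  expect_identical(out$tau, 0)
})

test_that("pure neo-Hookean phase reproduces the plane-strain closed form", {
  mat <- material_params(c_neo = 3.7)
  lam <- seq(0.7, 1.6, by = 0.1)
  pts <- tibble::tibble(lam_r = 1 / lam, lam_th = lam, lam_z = 1,
                        phi_c = 0, phi_p = 1, phi_e = 0)
  out <- passive_stress_deviatoric(pts, mat)
  expect_equal(out$Tth_hat - out$Trr_hat, 3.7 * (lam^2 - 1 / lam^2),
               tolerance = 1e-12)
})

test_that("analytic stress differences match finite differences of the strain energy", {
  mat <- material_params(alpha = 25 * pi / 180)
  h <- 1e-6
  set.seed(42)
  for (i in 1:20) {
    lth <- runif(1, 0.85, 1.6)
    lz <- runif(1, 0.9, 1.2)
    phi <- runif(3)
    phi <- phi / sum(phi) * 0.3
    pts <- tibble::tibble(lam_r = 1 / (lth * lz), lam_th = lth, lam_z = lz,
                          phi_c = phi[1], phi_p = phi[2], phi_e = phi[3])
    out <- passive_stress_deviatoric(pts, mat)

    W <- function(a, b) oracle_mixture_energy(a, b, phi[1], phi[2], phi[3], mat)
    dW_dlth <- (W(lth + h, lz) - W(lth - h, lz)) / (2 * h)
    dW_dlz <- (W(lth, lz + h) - W(lth, lz - h)) / (2 * h)
    # standard incompressible identities: Tth - Trr = lam_th dW/dlam_th,
    # Tzz - Trr = lam_z dW/dlam_z (radial stretch eliminated)
    expect_equal(out$Tth_hat - out$Trr_hat, lth * dW_dlth,
                 tolerance = 1e-6)
    expect_equal(out$Tzz_hat - out$Trr_hat, lz * dW_dlz,
                 tolerance = 1e-6)
  }
})

test_that("collagen bears no load below the recruitment stretch", {
  lu <- 1.25
  mat_a <- material_params(lambda_u = lu, k1_e = 8)
  mat_b <- material_params(lambda_u = lu, k1_e = 80)
  # choose lam_th so the fibre stretch sqrt(I4) sits just below lambda_u
  lth_below <- sqrt(((lu - 0.01)^2 - sin(mat_a$alpha)^2) /
                      cos(mat_a$alpha)^2)
  pts <- tibble::tibble(lam_r = 1 / lth_below, lam_th = lth_below, lam_z = 1,
                        phi_c = 0, phi_p = 0, phi_e = 1)
  sa <- passive_stress_deviatoric(pts, mat_a)
  sb <- passive_stress_deviatoric(pts, mat_b)
  expect_identical(sa$Tth_hat, sb$Tth_hat) # k1_e has no effect below lambda_u
  I4 <- lth_below^2 * cos(mat_a$alpha)^2 + sin(mat_a$alpha)^2
  expect_lt(sqrt(I4), lu)

  lth_above <- 1.5
  pts2 <- tibble::tibble(lam_r = 1 / lth_above, lam_th = lth_above, lam_z = 1,
                         phi_c = 0, phi_p = 0, phi_e = 1)
  expect_gt(passive_stress_deviatoric(pts2, mat_b)$Tth_hat,
            passive_stress_deviatoric(pts2, mat_a)$Tth_hat)
})

test_that("fibre stress projects the two symmetric helical families", {
  # homogeneous state with zero passive stress: tau reduces to the active
  # projection phi_c A_c (cos^4 + sin^4)
  for (alpha in c(0, pi / 4, 0.3)) {
    mat <- material_params(alpha = alpha, T_c = 2, K_d = 1, n_hill = 2)
    pts <- tibble::tibble(lam_r = 1, lam_th = 1, lam_z = 1,
                          phi_c = 0.3, phi_p = 0, phi_e = 0, k = 3)
    out <- total_stress(pts, mat)
    A_c <- 1.8
    expect_equal(out$tau, 0.3 * A_c * (cos(alpha)^4 + sin(alpha)^4),
                 tolerance = 1e-12)
  }
  # alpha = pi/4 halves the projected force density
  mat45 <- material_params(alpha = pi / 4, T_c = 2, K_d = 1, n_hill = 2)
  pts <- tibble::tibble(lam_r = 1, lam_th = 1, lam_z = 1,
                        phi_c = 0.3, phi_p = 0, phi_e = 0, k = 3)
  expect_equal(total_stress(pts, mat45)$tau, 0.3 * 1.8 / 2,
               tolerance = 1e-12)
})

test_that("kinematic and volume-fraction preconditions are enforced", {
  mat <- material_params()
  bad_inc <- tibble::tibble(lam_r = 1.2, lam_th = 1.2, lam_z = 1,
                            phi_c = 0.1, phi_p = 0.1, phi_e = 0.1)
  expect_error(passive_stress_deviatoric(bad_inc, mat),
               class = "airwaymorph_input_error")
  bad_phi <- tibble::tibble(lam_r = 1, lam_th = 1, lam_z = 1,
                            phi_c = -0.2, phi_p = 0.1, phi_e = 0.1)
  expect_error(passive_stress_deviatoric(bad_phi, mat),
               class = "airwaymorph_input_error")
})
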