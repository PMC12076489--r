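test_that("Rayleigh reduction follows the toluene-reference equation", {
  expect_equal(rayleigh_ratio(100, 100, 1e5), 0)
  # one toluene-equivalent excess: R_tol * (n_s/n_t)^2
  expect_equal(rayleigh_ratio(2e5, 1e5, 1e5),
               2.1e-2 * (1.333 / 1.497)^2, tolerance = 1e-12)
  expect_equal(rayleigh_ratio(2e5, 1e5, 1e5), 1.665e-2, tolerance = 1e-4)
  # affine in I_sample: doubling the excess doubles R
  r1 <- rayleigh_ratio(1.5e5, 1e5, 1e5)
  r2 <- rayleigh_ratio(2.0e5, 1e5, 1e5)
  expect_equal(r2, 2 * r1, tolerance = 1e-12)
  # homogeneous of degree -1 in I_toluene at fixed excess
  expect_equal(rayleigh_ratio(2e5, 1e5, 2e5), r1, tolerance = 1e-12)
  expect_error(rayleigh_ratio(1, 0, 0), "I_toluene")
  expect_warning(rayleigh_ratio(0.5e5, 1e5, 1e5), "negative excess")
})

test_that("q conversion and bounds", {
  expect_equal(q_from_angle(90), 4 * pi * 1.333 * sin(pi / 4) / 532,
               tolerance = 1e-12)
  expect_equal(round(q_from_angle(90), 4), 0.0223)
  expect_lt(q_from_angle(0.001), 1e-6)
  expect_error(q_from_angle(180), "strictly inside")
  expect_error(q_from_angle(0), "strictly inside")
})

test_that("power-law fitting recovers exact exponents", {
  q <- exp(seq(log(0.01), log(0.1), length.out = 20))
  expect_equal(fit_power_law(q, 5 * q^-1)$exponent, -1, tolerance = 1e-10)
  expect_equal(fit_power_law(q, 3 * q^0)$exponent, 0, tolerance = 1e-10)
  expect_equal(fit_power_law(q, 2 * q^-2)$exponent, -2, tolerance = 1e-10)
  expect_error(fit_power_law(q[1:3], (5 * q^-1)[1:3]), "at least 4")
  expect_error(fit_power_law(q, q - 0.05), "positive")
})

test_that("SLS simulator inverts through reduction to the target power law", {
  scan <- simulate_sls_scan(exponent = -1, amplitude = 1e-4,
                            noise_rel = 0)
  red <- reduce_sls(scan)
  pl <- fit_power_law(red$q_inv_nm, red$R_inv_m)
  expect_equal(pl$exponent, -1, tolerance = 1e-10)
  expect_equal(pl$amplitude, 1e-4, tolerance = 1e-10)
  # zero amplitude: sample equals solvent
  s0 <- simulate_sls_scan(amplitude = 0)
  expect_equal(s0$I_sample, s0$I_solvent, tolerance = 1e-12)
  # flat scatterer
  sf <- simulate_sls_scan(exponent = 0, noise_rel = 0)
  rf <- reduce_sls(sf)
  expect_equal(fit_power_law(rf$q_inv_nm, rf$R_inv_m)$exponent, 0,
               tolerance = 1e-10)
})

test_that("elliptical model matches the circular oracle at axis ratio 1", {
  q <- exp(seq(log(3e-3), log(0.4), length.out = 40))
  p <- ellipse_cyl_params(r_minor = 15, axis_ratio = 1, length = 300,
                          scale = 2, background = 0.05)
  Ie <- elliptical_cylinder_intensity(p, q)
  Ic <- circular_cylinder_intensity(15, 300, 2, 0.05, q)
  expect_lt(max(abs(Ie - Ic)), 1e-8)
})

test_that("form factor normalizes to scale + background at low q", {
  p <- ellipse_cyl_params(10, 1.87, 200, scale = 3, background = 0.2)
  expect_equal(elliptical_cylinder_intensity(p, 1e-7), 3.2,
               tolerance = 1e-9)
  # form factor in (0, 1]: intensity within (background, scale+background]
  q <- exp(seq(log(1e-3), log(0.5), length.out = 30))
  I <- elliptical_cylinder_intensity(p, q)
  expect_true(all(I > 0.2) && all(I <= 3.2 + 1e-12))
})

test_that("quadrature is converged at the default orders", {
  q <- exp(seq(log(5e-3), log(0.3), length.out = 25))
  p <- ellipse_cyl_params(10, 1.5, 200)
  I1 <- elliptical_cylinder_intensity(p, q, n_alpha = 128, n_phi = 64)
  I2 <- elliptical_cylinder_intensity(p, q, n_alpha = 256, n_phi = 128)
  expect_lt(max(abs(I1 - I2) / I2), 1e-6)
  Ic1 <- circular_cylinder_intensity(10, 200, 1, 0, q, n_alpha = 128)
  Ic2 <- circular_cylinder_intensity(10, 200, 1, 0, q, n_alpha = 256)
  expect_lt(max(abs(Ic1 - Ic2) / Ic2), 1e-6)
})

test_that("long cylinders show the q^-1 regime", {
  p <- ellipse_cyl_params(r_minor = 5, axis_ratio = 1.87, length = 5e4)
  qm <- exp(seq(log(10 / 5e4), log(0.5 / (5 * 1.87)), length.out = 15))
  pl <- fit_power_law(qm, elliptical_cylinder_intensity(p, qm))
  expect_equal(pl$exponent, -1, tolerance = 0.02)
})

test_that("elliptical fit recovers the generating cross-section", {
  truth <- ellipse_cyl_params(r_minor = 15, axis_ratio = 1.87,
                              length = 5000, scale = 1)
  crv <- simulate_sans_curve(truth, noise_rel = 0)
  init <- ellipse_cyl_params(12, 1.3, 5000, scale = max(crv$I))
  fit <- fit_elliptical_cylinder(crv$q_inv_A, crv$I, init)
  expect_true(fit$converged)
  expect_equal(fit$params$axis_ratio, 1.87, tolerance = 0.01 / 1.87)
  expect_equal(fit$params$r_minor, 15, tolerance = 1e-2)
  expect_equal(fit$params$scale, 1, tolerance = 1e-2)
  # circular truth drives the axis ratio to its lower bound
  circ <- simulate_sans_curve(
    ellipse_cyl_params(15, 1, 5000), noise_rel = 0)
  fc <- fit_elliptical_cylinder(circ$q_inv_A, circ$I,
                                ellipse_cyl_params(12, 1.4, 5000,
                                                   scale = max(circ$I)))
  expect_equal(fc$params$axis_ratio, 1, tolerance = 5e-3)
})

test_that("noisy cross-section recovery is stable over replicates", {
  truth <- ellipse_cyl_params(15, 1.87, 5000)
  ars <- vapply(1:5, function(sd) {
    crv <- simulate_sans_curve(truth, noise_rel = 0.02, seed = sd)
    fit_elliptical_cylinder(
      crv$q_inv_A, crv$I,
      ellipse_cyl_params(12, 1.3, 5000,
                         scale = max(crv$I)))$params$axis_ratio
  }, numeric(1))
  expect_lt(abs(median(ars) - 1.87) / 1.87, 0.05)
})

test_that("axis ratio rounds to monomers per cross-section", {
  expect_equal(cross_section_monomer_count(1.87), 2L)
  expect_equal(cross_section_monomer_count(1.0), 1L)
  expect_equal(cross_section_monomer_count(2.6), 3L)
  expect_equal(cross_section_monomer_count(
    ellipse_cyl_params(10, 1.87, 100)), 2L)
})
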