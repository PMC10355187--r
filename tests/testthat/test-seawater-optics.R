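test_that("pure-water constants default to the 532 nm values and validate", {
  w <- pure_water_optics()
  expect_equal(w$a_w, 0.042)
  expect_equal(w$b_w, 0.0022)
  expect_equal(w$b_bw, 0.0011)
  expect_error(pure_water_optics(b_w = 0.001, b_bw = 0.002), "b_bw")
})

test_that("power-law size distribution follows N0 (D/D0)^-xi", {
  psd <- power_law_psd(N0 = 1e10, D0 = 1, xi = 4)
  expect_equal(psd_number_density(psd, 1), 1e10)
  expect_equal(psd_number_density(psd, 2), 6.25e8)
  # log-log slope over a wide diameter range recovers -xi exactly
  D <- 10^seq(-1, 2, length.out = 50)
  sl <- coef(lm(log(psd_number_density(psd, D)) ~ log(D)))[2]
  expect_equal(unname(sl), -4, tolerance = 1e-10)
  expect_error(psd_number_density(psd, c(1, -2)), "positive")
  expect_error(power_law_psd(xi = 3), "xi")
})

test_that("refractive index relation m = 1.01 + 0.1542 (xi - 3)", {
  expect_equal(relative_refractive_index(4), 1.1642)
  expect_equal(relative_refractive_index(3.38), 1.068596)
  expect_equal(relative_refractive_index(3.0001), 1.01, tolerance = 1e-4)
  expect_error(relative_refractive_index(3), "xi")
  expect_true(all(diff(relative_refractive_index(seq(3.1, 5, 0.1))) > 0))
})

test_that("phase function is normalized, forward-peaked, and nonnegative", {
  for (xi in c(3.2, 3.5, 4)) {
    # closed-form cumulative reaches exactly 1 at 180 degrees
    expect_equal(fournier_forand_cdf(pi, xi), 1, tolerance = 1e-12)
    # independent quadrature oracle for the full-sphere normalization
    expect_equal(ff_quad_cdf(pi, xi), 1, tolerance = 1e-6)
    th <- seq(1e-4, pi, length.out = 200)
    expect_true(all(fournier_forand_phase(th, xi) >= 0))
  }
  expect_gt(fournier_forand_phase(pi / 180, 3.5) /
              fournier_forand_phase(pi / 2, 3.5), 1e3)
  expect_error(fournier_forand_phase(0, 3.5), "singular")
})

test_that("closed-form cumulative matches quadrature across angles", {
  for (xi in c(3.05, 3.15, 3.35, 3.42, 4, 5)) {
    for (th in c(0.01, 0.1, 0.5, pi / 2, 2.5)) {
      expect_equal(fournier_forand_cdf(th, xi), ff_quad_cdf(th, xi),
                   tolerance = 1e-6)
    }
  }
})

test_that("backscatter fraction equals the backward-hemisphere integral", {
  for (xi in c(3.1, 3.15, 3.35, 3.5, 4, 4.5)) {
    quad <- stats::integrate(function(t) {
      fournier_forand_phase(t, xi) * 2 * pi * sin(t)
    }, pi / 2, pi, rel.tol = 1e-10)$value
    expect_equal(backscatter_fraction(xi), quad, tolerance = 0.01)
    expect_equal(backscatter_fraction(xi), 1 - fournier_forand_cdf(pi / 2, xi),
                 tolerance = 1e-12)
    expect_gt(backscatter_fraction(xi), 0)
    expect_lt(backscatter_fraction(xi), 0.5)
  }
  # canonical Petzold-like pairing
  expect_equal(backscatter_fraction(3.5835), 0.0183, tolerance = 1e-3)
  # larger xi (smaller particles) backscatters a larger fraction
  expect_true(backscatter_fraction(3.2) < backscatter_fraction(3.6))
  expect_true(backscatter_fraction(3.6) < backscatter_fraction(4.0))
  expect_error(backscatter_fraction(3), "xi")
})

test_that("backscatter-fraction inversion round-trips the profile", {
  prof <- quick_profile(b = 0.5, xi = 3.3)
  bb <- profile_backscatter(prof)
  bf <- bb$b_bp / (prof$b - pure_water_optics()$b_w)
  expect_equal(xi_from_backscatter_fraction(bf), prof$xi, tolerance = 1e-6)
})

test_that("molecular phase is normalized and symmetric about 90 degrees", {
  quad <- stats::integrate(function(t) molecular_phase(t) * 2 * pi * sin(t),
                           0, pi, rel.tol = 1e-10)$value
  expect_equal(quad, 1, tolerance = 1e-8)
  th <- seq(0, pi / 2, length.out = 50)
  expect_equal(molecular_phase(th), molecular_phase(pi - th))
  expect_equal(molecular_phase_cdf(pi / 2), 0.5)
})

test_that("scattering-angle sampling is reproducible and matches the CDF", {
  ph <- list(type = "fournier_forand", xi = 3.5)
  expect_error(sample_scattering_angle(10, ph), "seed")
  d1 <- sample_scattering_angle(1000, ph, seed = 42)
  d2 <- sample_scattering_angle(1000, ph, seed = 42)
  expect_identical(d1, d2)

  n <- 1e6
  draws <- sample_scattering_angle(n, ph, seed = 7)
  ks <- max(abs(fournier_forand_cdf(sort(draws), 3.5) - (1:n) / n))
  expect_lt(ks, 0.005)
  # fraction beyond 90 degrees matches BF within 3 binomial standard errors
  bf <- backscatter_fraction(3.5)
  expect_lt(abs(mean(draws > pi / 2) - bf), 3 * sqrt(bf * (1 - bf) / n))

  dm <- sample_scattering_angle(1e5, "molecular", seed = 9)
  ksm <- max(abs(molecular_phase_cdf(sort(dm)) - (1:1e5) / 1e5))
  expect_lt(ksm, 0.01)
})
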