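config <- test_config()
water <- pure_water_optics()

test_that("K_d estimate is scale invariant and meets the clear-water limit", {
  prof <- iop_profile(seq(0.5, 9.5), rep(water$a_w, 10), rep(water$b_w, 10),
                      rep(3.35, 10))
  # bin-center evaluation: the range-corrected log signal is exactly linear
  sig <- forward_analytic(prof, config, nsub = 1)
  kd <- estimate_kd(sig, config)
  ok <- is.finite(kd)
  expect_equal(kd[ok], rep(water$a_w + water$b_w, sum(ok)), tolerance = 1e-6)
  # multiplying the signal by a constant leaves K_d unchanged
  scaled <- signal_set(sig$depths, sig$mol * 7.3, sig$comb_wide * 7.3)
  expect_equal(estimate_kd(scaled, config), kd)
})

test_that("K_d of turbid water sits between absorption and beam attenuation", {
  prof <- quick_profile(a = 0.11, b = 0.75, xi = 3.15, depth = 8)
  sig <- forward_analytic(prof, config)
  kd <- estimate_kd(sig, config)
  ok <- is.finite(kd)
  expect_true(all(kd[ok] > prof$a[ok]))
  expect_true(all(kd[ok] < prof$a[ok] + prof$b[ok]))
})

test_that("b_bp estimation inverts the channel ratio", {
  prof <- quick_profile(b = 0.5, xi = 3.3, depth = 6)
  sig <- forward_analytic(prof, config)
  bb <- estimate_bbp(sig, config, chi = 1.1)
  # identical channels mean zero particulate return
  none <- signal_set(sig$depths, sig$mol,
                     sig$mol[, "mol_wide"])
  expect_equal(estimate_bbp(none, config)$bbp, rep(0, length(sig$depths)))
  # the noiseless analytic ratio encodes beta_p(pi) = b_p p_ff(pi) exactly
  beta_expected <- (prof$b - water$b_w) *
    fournier_forand_phase(pi, prof$xi[1])
  expect_equal(bb$beta_p_180, beta_expected, tolerance = 1e-8)
})

test_that("b_bp estimates are monotone in the true particulate backscatter", {
  got <- vapply(c(0.3, 0.45, 0.6, 0.75), function(b) {
    sig <- forward_analytic(quick_profile(b = b, xi = 3.3, depth = 5), config)
    mean(estimate_bbp(sig, config)$bbp)
  }, numeric(1))
  expect_true(all(diff(got) > 0))
})

test_that("lidar ratio follows its defining identities", {
  kd_pure <- water$a_w + water$b_bw
  expect_equal(lidar_ratio(kd_pure, 0.001), 0)
  expect_equal(lidar_ratio(0.15, 0.002), 2 * lidar_ratio(0.15, 0.004))
  expect_true(is.na(lidar_ratio(0.15, 0)))
  # L1-like and L5-like waters are separable by (R, omega0)
  r_of <- function(sc) {
    prof <- make_profile(scenario_spec(sc, depth_max = 6))
    sig <- forward_analytic(prof, config)
    pr <- derive_products(sig, config, retrieved = prof)
    colMeans(pr[3:5, c("lidar_ratio", "omega0")], na.rm = TRUE)
  }
  r1 <- r_of("L1"); r5 <- r_of("L5")
  expect_gt(abs(r1[1] - r5[1]) / r5[1], 0.2)
})

test_that("single-scattering albedo identities", {
  expect_equal(single_scattering_albedo(0.11, 0.75), 0.9166, tolerance = 1e-3)
  expect_equal(single_scattering_albedo(water$a_w, 0.5), 1)
  expect_true(is.na(single_scattering_albedo(water$a_w, water$b_w)))
  expect_lt(single_scattering_albedo(0.11, 0.3),
            single_scattering_albedo(0.08, 0.3))
  expect_lt(single_scattering_albedo(0.08, 0.3),
            single_scattering_albedo(0.08, 0.5))
  omega <- single_scattering_albedo(0.0421, 0.0023)
  expect_gt(omega, 0); expect_lt(omega, 1)
})

test_that("backscattering wavelength conversion is lambda0/lambda", {
  expect_equal(bbp_wavelength_convert(0.00522, 510, 532), 0.00522 * 510 / 532)
  expect_equal(bbp_wavelength_convert(0.003, 532, 532), 0.003)
  expect_equal(bbp_wavelength_convert(0.003, 532, 266), 0.006)
})
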