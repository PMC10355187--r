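config <- test_config()
water <- pure_water_optics()

# closed-form single-scattering lidar equation (molecular return only)
single_scatter_oracle <- function(depths, a, b_w, config) {
  amp <- config$system_constant * pi * config$receiver_radius^2 *
    molecular_beta_pi(config$water, config$mol_depol)
  amp / (config$lidar_height + depths)^2 * exp(-2 * (a + b_w) * depths)
}

test_that("analytic model reduces to the lidar equation without particles", {
  prof <- iop_profile(seq(0.5, 9.5), rep(water$a_w, 10), rep(water$b_w, 10),
                      rep(3.35, 10))
  sig <- forward_analytic(prof, config, nsub = 1)
  oracle <- single_scatter_oracle(prof$depth, water$a_w, water$b_w, config)
  for (ch in 1:3) {
    expect_equal(sig$mol[, ch], oracle, tolerance = 1e-10)
  }
})

test_that("noiseless channels are nested and decay with depth", {
  sig <- forward_analytic(quick_profile(depth = 10), config)
  expect_true(all(sig$mol[, "mol_wide"] >= sig$mol[, "mol_mid"]))
  expect_true(all(sig$mol[, "mol_mid"] >= sig$mol[, "mol_narrow"]))
  expect_true(all(sig$comb_wide >= sig$mol[, "mol_wide"]))
  expect_true(all(diff(sig$mol[, "mol_wide"]) < 0))
})

test_that("analytic log-slopes honor the narrow/wide attenuation ordering", {
  prof <- quick_profile(a = 0.11, b = 0.75, xi = 3.15, depth = 8)
  sig <- forward_analytic(prof, config)
  rc <- function(ch) log(sig$mol[, ch] * (config$lidar_height + sig$depths)^2)
  k_n <- -diff(rc("mol_narrow")) / 2
  k_w <- -diff(rc("mol_wide")) / 2
  c_beam <- prof$a[1] + prof$b[1]
  expect_true(all(k_n > k_w))          # narrow sees more attenuation
  expect_true(all(k_w >= prof$a[1]))   # wide stays above absorption
  expect_true(all(k_n <= c_beam))      # never exceeds beam attenuation
  # shrinking the FOVs drives the slope monotonically up to the beam
  # attenuation; the approach is slow because the Fournier-Forand forward
  # spike concentrates scattering at micro-angles, so the limit is only
  # reached for absurdly small apertures
  k_at <- function(f) {
    cf <- lidar_config(fovs = f)
    mean(-diff(log(forward_analytic(prof, cf)$mol[, 1] *
                     (cf$lidar_height + sig$depths)^2)) / 2)
  }
  k_small <- k_at(c(4e-4, 8e-4, 2e-3))
  k_tiny <- k_at(c(1e-12, 2e-12, 4e-12))
  expect_gt(k_small, mean(k_n))
  expect_gt(k_tiny, k_small)
  expect_equal(k_tiny, c_beam, tolerance = 0.05)
})

test_that("Monte Carlo is reproducible and matches pure-water closed form", {
  prof <- iop_profile(seq(0.5, 7.5), rep(water$a_w, 8), rep(water$b_w, 8),
                      rep(3.35, 8))
  mc1 <- simulate_mc(prof, config, n_photons = 5e4, seed = 31)
  mc2 <- simulate_mc(prof, config, n_photons = 5e4, seed = 31)
  expect_identical(mc1$mol, mc2$mol)
  expect_identical(mc1$comb_wide, mc2$comb_wide)
  mc3 <- simulate_mc(prof, config, n_photons = 5e4, seed = 32)
  expect_false(identical(mc1$mol, mc3$mol))

  # pure water: two-way log-slope equals 2 (a_w + b_w) within 3 MC SEs
  mc <- cached("mc_pure", simulate_mc(prof, config, n_photons = 4e5, seed = 5))
  rc <- log(mc$mol[, "mol_wide"] * (config$lidar_height + prof$depth)^2)
  fit <- lm(rc ~ prof$depth)
  slope_se <- summary(fit)$coefficients[2, 2]
  expect_lt(abs(unname(coef(fit)[2]) + 2 * (water$a_w + water$b_w)),
            3 * slope_se + 1e-4)
})

test_that("MC standard error scales roughly as photons^(-1/2)", {
  prof <- quick_profile(depth = 5)
  se_at <- function(n) {
    mc <- simulate_mc(prof, config, n_photons = n, seed = 17)
    mean(mc$meta$mol_se[1:4, "mol_wide"] / mc$mol[1:4, "mol_wide"])
  }
  ratio <- se_at(2e4) / se_at(3.2e5)
  expect_gt(ratio, 4 / 2.0)   # expect about sqrt(16) = 4
  expect_lt(ratio, 4 * 2.0)
})

test_that("multiple-scattering FOV gap grows with optical depth and vanishes
           in clear water", {
  turbid <- forward_analytic(quick_profile(a = 0.11, b = 0.75, xi = 3.15,
                                           depth = 8), config)
  gap <- (turbid$mol[, "mol_wide"] - turbid$mol[, "mol_narrow"]) /
    turbid$mol[, "mol_narrow"]
  expect_true(all(diff(gap) > 0))
  clearp <- iop_profile(seq(0.5, 7.5), rep(water$a_w, 8), rep(water$b_w, 8),
                        rep(3.35, 8))
  clear <- forward_analytic(clearp, config)
  gap_clear <- (clear$mol[, "mol_wide"] - clear$mol[, "mol_narrow"]) /
    clear$mol[, "mol_narrow"]
  expect_lt(max(abs(gap_clear)), 1e-10)
})

test_that("Poisson noise behaves: reproducible, unbiased, right variance", {
  sig <- forward_analytic(quick_profile(depth = 5), config)
  n1 <- add_noise(sig, scale = 1e4 / max(sig$mol), seed = 3)
  n2 <- add_noise(sig, scale = 1e4 / max(sig$mol), seed = 3)
  expect_identical(n1$mol, n2$mol)
  expect_error(add_noise(sig, scale = -1, seed = 1), "positive")
  expect_error(add_noise(sig, scale = 1, background = -2, seed = 1),
               "background")

  # enormous photon budget recovers the input to 0.1%
  hi <- add_noise(sig, scale = 1e9 / min(sig$mol), seed = 4)
  expect_equal(hi$mol, sig$mol, tolerance = 1e-3)

  # variance of repeated draws matches mean/scale (Poisson property)
  scale <- 2e3 / sig$mol[1, "mol_wide"]
  draws <- vapply(1:400, function(k) {
    add_noise(sig, scale = scale, seed = 100 + k)$mol[1, "mol_wide"]
  }, numeric(1))
  expect_equal(var(draws), unname(sig$mol[1, "mol_wide"] / scale),
               tolerance = 0.25)
})

test_that("analytic and MC forward models agree over three optical depths", {
  for (sc in c("L1", "L5")) {
    prof <- make_profile(scenario_spec(sc, depth_max = 8))
    mc <- cached(paste0("mc_", sc),
                 simulate_mc(prof, config, n_photons = 2e6, seed = 21))
    an <- forward_analytic(prof, config)
    c_beam <- prof$a[1] + prof$b[1]
    use <- which(c_beam * prof$depth <= 3)
    for (ch in 1:3) {
      reldiff <- abs(an$mol[use, ch] / mc$mol[use, ch] - 1)
      expect_lt(max(reldiff), 0.15)
    }
  }
})
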