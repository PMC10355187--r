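config <- test_config()

test_that("presets encode the nearshore-to-offshore survey values", {
  p1 <- make_profile(scenario_spec("L1"))
  expect_equal(unique(p1$a), 0.11)
  expect_equal(unique(p1$b), 0.75)
  expect_equal(unique(p1$xi), 3.15)
  p5 <- make_profile(scenario_spec("L5"))
  expect_equal(unique(p5$a), 0.047)
  expect_equal(unique(p5$b), 0.25)
  expect_equal(unique(p5$xi), 3.42)
  # turbidity decreases offshore while the PSD slope increases
  pres <- scenario_presets()
  bs <- vapply(pres, `[[`, numeric(1), "b")
  xis <- vapply(pres, `[[`, numeric(1), "xi")
  expect_lt(cor(bs, xis), 0)
  expect_error(scenario_spec("L7"), "unknown")
  expect_error(scenario_spec("custom", a = 3, b = 0.4, xi = 3.3), "bounds")
})

test_that("layered specifications produce exact piecewise profiles", {
  spec <- scenario_spec("custom", a = 0.08, b = 0.4, xi = 3.3, depth_max = 10,
                        gradients = list(breaks = c(4, 10),
                                         a = c(0.06, 0.09),
                                         b = c(0.3, 0.5),
                                         xi = c(3.4, 3.2)))
  prof <- make_profile(spec)
  expect_equal(prof$a, c(rep(0.06, 4), rep(0.09, 6)))
  expect_equal(prof$b, c(rep(0.3, 4), rep(0.5, 6)))
  expect_equal(prof$xi, c(rep(3.4, 4), rep(3.2, 6)))
  strat <- make_profile(scenario_spec("L4", stratified = TRUE))
  expect_lt(strat$b[1], strat$b[10])
  expect_gt(strat$xi[1], strat$xi[10])
})

test_that("ensembles are reproducible, valid, and span the parameter box", {
  e1 <- make_ensemble(n = 20, seed = 11)
  e2 <- make_ensemble(n = 20, seed = 11)
  expect_identical(e1, e2)
  surf <- t(vapply(e1, function(p) unlist(p[1, c("a", "b", "xi")]),
                   numeric(3)))
  w <- pure_water_optics()
  for (p in e1) {
    expect_s3_class(p, "iop_profile")
    expect_true(all(p$a >= w$a_w & p$b >= w$b_w & p$xi > 3 & p$xi <= 5))
  }
  rng <- list(a = c(0.047, 0.110), b = c(0.25, 0.75), xi = c(3.15, 3.42))
  for (k in 1:3) {
    span <- diff(range(surf[, k])) / diff(rng[[k]])
    expect_gt(span, 0.9)
  }
  # a fixed fraction of members carries the stratified surface layer
  strat <- vapply(e1, function(p) p$b[1] != p$b[nrow(p)], logical(1))
  expect_equal(sum(strat), 4)
  expect_error(make_ensemble(n = 5, ranges = list(a = c(0.05, 0.05),
                                                  b = c(0.25, 0.75),
                                                  xi = c(3.15, 3.42))),
               "min < max")
})

test_that("fixtures pair reproducible signals with their generating truth", {
  spec <- scenario_spec("L3", depth_max = 5, seed = 77L)
  f1 <- make_fixture(spec, config, n_photons = 2e4)
  f2 <- make_fixture(spec, config, n_photons = 2e4)
  expect_identical(f1$signals$mol, f2$signals$mol)
  expect_identical(as.data.frame(f1$truth),
                   as.data.frame(make_profile(spec, config$bin_size)))
  noisy <- make_fixture(scenario_spec("L3", depth_max = 5, seed = 78L,
                                      noise = list(scale = 1e8)),
                        config, n_photons = 2e4)
  expect_true(all(noisy$signals$mol >= 0))
})
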