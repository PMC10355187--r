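config <- test_config()

test_that("rmsrd implements the root-mean-square relative difference", {
  expect_equal(rmsrd(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmsrd(rep(1.1, 5), rep(1, 5)), 10)
  expect_equal(rmsrd(c(0.9, 1.1), c(1, 1)), 10)
  expect_error(rmsrd(1:3, 1:2), "length")
  expect_error(rmsrd(c(1, 2), c(1, 0)), "nonzero")
})

test_that("initialization estimates attenuation-based first guesses", {
  prof <- quick_profile(a = 0.08, b = 0.45, xi = 3.3, depth = 10)
  sig <- forward_analytic(prof, config)
  init <- initialize_state(sig, config)
  # default PSD slope start is constant 3.5
  expect_true(all(init$xi == 3.5))
  # a0 approximates the wide-FOV (diffuse-like) attenuation within 10%
  kd <- estimate_kd(sig, config)
  ok <- is.finite(kd)
  expect_lt(max(abs(init$a[ok] / kd[ok] - 1)), 0.10)
  # b floor: pure-water profile cannot produce b0 below b_w
  w <- pure_water_optics()
  clearp <- iop_profile(seq(0.5, 9.5), rep(w$a_w, 10), rep(w$b_w, 10),
                        rep(3.35, 10))
  init_clear <- initialize_state(forward_analytic(clearp, config), config)
  expect_true(all(init_clear$b >= w$b_w))
})

test_that("sensitivity matrix has lidar causality structure", {
  prof <- quick_profile(depth = 6)
  S <- compute_sensitivity(prof, config)
  n <- nrow(prof)
  expect_equal(dim(S), c(3 * n, 3 * n))
  # perturbing the bottom bin leaves all shallower signals unchanged
  for (ch in 0:2) {
    for (p in 0:2) {
      expect_equal(unname(S[ch * n + seq_len(n - 1), p * n + n]), rep(0, n - 1))
    }
  }
  # increasing absorption in the top bin dims every channel below it
  expect_true(all(S[seq_len(3 * n)[-c(1, n + 1, 2 * n + 1)], 1] < 0))
})

test_that("sensitivity differencing is converged in the step size", {
  prof <- quick_profile(depth = 4)
  S1 <- compute_sensitivity(prof, config, step = 0.02)
  S2 <- compute_sensitivity(prof, config, step = 0.01)
  big <- abs(S1) > 0.1 * max(abs(S1))
  expect_lt(max(abs(S1[big] / S2[big] - 1)), 0.01)
})

test_that("retrieval is a fixed point at the truth", {
  prof <- quick_profile(depth = 6)
  sig <- forward_analytic(prof, config)
  res <- iterate_retrieval(sig, config, init = prof)
  expect_true(res$converged)
  expect_equal(res$n_iterations, 0)
  expect_lt(res$rmsrd_final, 0.01)
})

test_that("noiseless self-inversion recovers 3-bin profiles within 1%", {
  for (vals in list(c(0.078, 0.40, 3.35), c(0.09, 0.5, 3.3),
                    c(0.1, 0.6, 3.4))) {
    prof <- quick_profile(a = vals[1], b = vals[2], xi = vals[3], depth = 3)
    sig <- forward_analytic(prof, config)
    res <- iterate_retrieval(sig, config, init = initialize_state(sig, config),
                             min_progress = 1e-4, max_iter = 60)
    err <- rmsrd_profiles(res$iop, prof)
    expect_lt(err$a, 1)
    expect_lt(err$b, 1)
    expect_lt(err$xi, 1)
  }
})

test_that("retrieved profiles respect physical bounds and diagnostics", {
  prof <- quick_profile(depth = 6)
  sig <- add_noise(forward_analytic(prof, config),
                   scale = 5e5 / max(forward_analytic(prof, config)$mol),
                   seed = 8)
  res <- iterate_retrieval(sig, config, max_iter = 10)
  w <- pure_water_optics()
  expect_true(all(res$iop$a >= w$a_w & res$iop$a <= 2))
  expect_true(all(res$iop$b >= w$b_w & res$iop$b <= 5))
  expect_true(all(res$iop$xi > 3 & res$iop$xi <= 5))
  expect_s3_class(res$trajectory, "data.frame")
  # accepted iterations make monotone progress in the minimized objective
  expect_true(all(diff(res$trajectory$cost) < 0))
  expect_named(res$rmsrd_by_fov, c("mol_narrow", "mol_mid", "mol_wide"))
})

test_that("usable depth honors the narrow-channel dynamic range", {
  prof <- quick_profile(a = 0.11, b = 0.75, xi = 3.2, depth = 15)
  sig <- forward_analytic(prof, config)
  res <- iterate_retrieval(sig, config, max_iter = 2)
  mn <- sig$mol[, "mol_narrow"]
  expect_equal(nrow(res$iop), sum(mn >= max(mn) / 1e3))
})
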