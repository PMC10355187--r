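# Shared fixtures: a compact instrument configuration and small profiles so
# unit tests stay fast; expensive shared computations are memoised in an
# environment so several test files can reuse them.

test_config <- function(...) lidar_config(...)

quick_profile <- function(a = 0.078, b = 0.40, xi = 3.35, depth = 6,
                          bin = 1) {
  make_profile(scenario_spec("custom", a = a, b = b, xi = xi,
                             depth_max = depth), bin_size = bin)
}

# memoised store for results shared across test blocks
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

# independent quadrature of the phase function over [0, theta]; the forward
# singularity is handled by the substitution s = psi^((xi-3)/2), under which
# the integrand is regular at the origin
ff_quad_cdf <- function(theta, xi) {
  kap <- (xi - 3) / 2
  head_end <- min(theta, 0.1)
  head <- stats::integrate(function(s) {
    psi <- s^(1 / kap)
    fournier_forand_phase(psi, xi) * 2 * pi * sin(psi) * psi / (kap * s)
  }, 0, head_end^kap, rel.tol = 1e-10, subdivisions = 2000L)$value
  tail <- if (theta > 0.1) {
    stats::integrate(function(t) fournier_forand_phase(t, xi) * 2 * pi * sin(t),
                     0.1, theta, rel.tol = 1e-10,
                     subdivisions = 2000L)$value
  } else 0
  head + tail
}
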