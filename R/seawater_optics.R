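# Seawater constituent optics: pure-water constants, power-law particle size
# distribution, Fournier-Forand phase function and backscatter fraction, and
# the Rayleigh-like molecular (Brillouin-channel) phase function.

#' Pure seawater optical constants
#'
#' Absorption, scattering, and backscattering coefficients of pure seawater at
#' the lidar wavelength. Defaults are the standard 532 nm values
#' (0.042, 0.0022, 0.0011 m^-1); temperature and salinity dependence is not
#' modelled.
#'
#' @param wavelength Wavelength in nm.
#' @param a_w Pure-seawater absorption coefficient, m^-1.
#' @param b_w Pure-seawater scattering coefficient, m^-1.
#' @param b_bw Pure-seawater backscattering coefficient, m^-1.
#' @return An object of class `pure_water_optics`.
#' @export
#' @examples
#' pure_water_optics()
pure_water_optics <- function(wavelength = 532, a_w = 0.042, b_w = 0.0022,
                              b_bw = 0.0011) {
  stopifnot(wavelength > 0, a_w >= 0, b_w >= 0, b_bw >= 0)
  if (b_bw > b_w) {
    stop("pure-water backscattering b_bw cannot exceed scattering b_w")
  }
  structure(list(wavelength = wavelength, a_w = a_w, b_w = b_w, b_bw = b_bw),
            class = "pure_water_optics")
}

#' @export
print.pure_water_optics <- function(x, ...) {
  cat(sprintf(
    "Pure seawater optics at %g nm: a_w = %g, b_w = %g, b_bw = %g m^-1\n",
    x$wavelength, x$a_w, x$b_w, x$b_bw))
  invisible(x)
}

#' Power-law (Junge-type) particle size distribution
#'
#' @param N0 Particle number concentration at the reference diameter,
#'   m^-3 um^-1.
#' @param D0 Reference diameter, um.
#' @param xi Dimensionless distribution slope; must lie in (3, 5].
#' @return An object of class `power_law_psd`.
#' @export
power_law_psd <- function(N0 = 1e10, D0 = 1, xi = 3.5) {
  stopifnot(N0 > 0, D0 > 0)
  check_xi(xi)
  structure(list(N0 = N0, D0 = D0, xi = xi), class = "power_law_psd")
}

check_xi <- function(xi) {
  if (any(!is.finite(xi)) || any(xi <= 3) || any(xi > 5)) {
    stop("PSD slope xi must lie in (3, 5]; xi <= 3 degenerates the ",
         "Fournier-Forand backscatter fraction (v = (3 - xi)/2 >= 0)")
  }
  invisible(xi)
}

#' Particle number concentration of a power-law size distribution
#'
#' Evaluates N(D) = N0 (D / D0)^(-xi).
#'
#' @param psd A [power_law_psd()] object.
#' @param D Particle diameter(s), um; must be positive.
#' @return Number concentration, m^-3 um^-1.
#' @export
#' @examples
#' psd_number_density(power_law_psd(1e10, 1, 4), D = 2)
psd_number_density <- function(psd, D) {
  stopifnot(inherits(psd, "power_law_psd"))
  if (any(!is.finite(D)) || any(D <= 0)) stop("diameter D must be positive")
  psd$N0 * (D / psd$D0)^(-psd$xi)
}

#' Relative refractive index implied by the PSD slope
#'
#' The particle refractive index relative to seawater is tied to the PSD slope
#' through the empirical linear relation m = 1.01 + 0.1542 (xi - 3), the
#' standard pairing used with the Fournier-Forand phase function.
#'
#' @param xi PSD slope in (3, 5].
#' @return Relative refractive index m (dimensionless).
#' @export
#' @examples
#' relative_refractive_index(3.38)
relative_refractive_index <- function(xi) {
  check_xi(xi)
  1.01 + 0.1542 * (xi - 3)
}

# Fournier-Forand parameter bundle shared by density/CDF evaluations.
# delta(psi) = u / K with u = sin^2(psi/2), K = 3 (m-1)^2 / 4, v = (3-xi)/2.
ff_params <- function(xi) {
  m <- relative_refractive_index(xi)
  K <- 3 * (m - 1)^2 / 4
  d180 <- 1 / K
  v <- (3 - xi) / 2
  list(m = m, K = K, v = v, d180 = d180,
       # coefficient of the large-angle (3 cos^2 - 1) correction term
       bcoef = (1 - d180^v) / (16 * pi * (d180 - 1) * d180^v))
}

#' Fournier-Forand scattering phase function
#'
#' Analytic phase function of a power-law ensemble of homogeneous spheres,
#' parameterized solely by the PSD slope `xi` through the refractive-index
#' relation m(xi). Normalized so that the integral over the full sphere,
#' `integral p(theta) 2 pi sin(theta) d theta`, equals 1.
#'
#' @param theta Scattering angle(s) in radians, in (0, pi]; the forward
#'   direction theta = 0 is singular and rejected.
#' @param xi PSD slope in (3, 5].
#' @return Phase density in sr^-1.
#' @export
fournier_forand_phase <- function(theta, xi) {
  check_xi(xi)
  if (any(!is.finite(theta)) || any(theta <= 0) || any(theta > pi)) {
    stop("scattering angle theta must lie in (0, pi]; the forward direction ",
         "theta = 0 is singular")
  }
  pp <- ff_params(xi)
  u <- sin(theta / 2)^2
  d <- u / pp$K
  v <- pp$v
  main <- 1 / (4 * pi * (1 - d)^2 * d^v) *
    (v * (1 - d) - (1 - d^v) + (d * (1 - d^v) - v * (1 - d)) / u)
  main + pp$bcoef * (3 * cos(theta)^2 - 1)
}

#' Cumulative Fournier-Forand scattering fraction
#'
#' Closed-form fraction of total scattering into angles `[0, theta]`,
#' i.e. the integral of [fournier_forand_phase()] times `2 pi sin(theta)`.
#' Satisfies F(pi) = 1 identically and
#' `backscatter_fraction(xi) == 1 - fournier_forand_cdf(pi/2, xi)`.
#'
#' @param theta Scattering angle(s) in radians, in `[0, pi]`.
#' @param xi PSD slope in (3, 5]. Either argument may be vectorized
#'   (recycled to a common length).
#' @return Cumulative scattered fraction in `[0, 1]`.
#' @export
fournier_forand_cdf <- function(theta, xi) {
  check_xi(xi)
  if (any(!is.finite(theta)) || any(theta < 0) || any(theta > pi + 1e-12)) {
    stop("theta must lie in [0, pi]")
  }
  n <- max(length(theta), length(xi))
  theta <- rep_len(theta, n)
  xi <- rep_len(xi, n)
  m <- 1.01 + 0.1542 * (xi - 3)
  K <- 3 * (m - 1)^2 / 4
  v <- (3 - xi) / 2
  d180 <- 1 / K
  u <- sin(theta / 2)^2
  d <- u / K
  main <- ifelse(u <= 0, 0,
                 (1 - d^(v + 1) - u * (1 - d^v)) / ((1 - d) * d^v))
  bterm <- (1 - d180^v) / (4 * (d180 - 1) * d180^v) *
    (2 * u - 6 * u^2 + 4 * u^3)
  pmin(pmax(main + bterm, 0), 1)
}

#' Particulate backscatter fraction from the PSD slope
#'
#' Closed-form Fournier-Forand backscatter fraction BF = b_bp / b_p, using the
#' intermediates delta90 = (4/3)(m-1)^-2 sin^2(45 deg) and v = (3 - xi)/2 with
#' m = m(xi). Equals the backward-hemisphere integral of the phase function.
#'
#' @param xi PSD slope in (3, 5].
#' @return Backscatter fraction, dimensionless, in (0, 0.5).
#' @export
#' @examples
#' backscatter_fraction(3.5835) # canonical Petzold-like value ~0.0183
backscatter_fraction <- function(xi) {
  check_xi(xi)
  m <- 1.01 + 0.1542 * (xi - 3)
  v <- (3 - xi) / 2
  d90 <- (4 / (3 * (m - 1)^2)) * sin(pi / 4)^2
  1 - (1 - d90^(v + 1) - 0.5 * (1 - d90^v)) / ((1 - d90) * d90^v)
}

#' Invert the backscatter fraction to a PSD slope
#'
#' Solves BF(xi) = bf for xi in (3, 5]. This mirrors the conversion applied to
#' in situ measurements, where xi is obtained by substituting measured b_p and
#' b_bp into the closed-form backscatter fraction.
#'
#' @param bf Backscatter fraction(s) in (BF(3+), BF(5)).
#' @param tol Root-finding tolerance on xi.
#' @return PSD slope xi.
#' @export
xi_from_backscatter_fraction <- function(bf, tol = 1e-10) {
  stopifnot(all(is.finite(bf)), all(bf > 0), all(bf < 0.5))
  vapply(bf, function(y) {
    lo <- 3 + 1e-9
    if (y <= backscatter_fraction(lo) || y >= backscatter_fraction(5)) {
      stop("backscatter fraction ", y, " outside the invertible range of BF(xi)")
    }
    uniroot(function(x) backscatter_fraction(x) - y, c(lo, 5), tol = tol)$root
  }, numeric(1))
}

#' Molecular (Brillouin-channel) scattering phase function
#'
#' Rayleigh-like phase function p(theta) proportional to 1 + f cos^2(theta),
#' normalized over the sphere. The factor `f` absorbs depolarization; the
#' default 0.835 is close to the depolarization-adjusted value for water.
#'
#' @param theta Scattering angle(s), radians, in `[0, pi]`.
#' @param depol_f Anisotropy factor f.
#' @return Phase density in sr^-1.
#' @export
molecular_phase <- function(theta, depol_f = 0.835) {
  stopifnot(depol_f >= 0)
  if (any(!is.finite(theta)) || any(theta < 0) || any(theta > pi + 1e-12)) {
    stop("theta must lie in [0, pi]")
  }
  (1 + depol_f * cos(theta)^2) / (4 * pi * (1 + depol_f / 3))
}

#' Cumulative molecular scattering fraction
#'
#' @inheritParams molecular_phase
#' @return Fraction of molecular scattering into `[0, theta]`.
#' @export
molecular_phase_cdf <- function(theta, depol_f = 0.835) {
  stopifnot(depol_f >= 0)
  mu <- cos(theta)
  ((1 - mu) + depol_f * (1 - mu^3) / 3) / (2 * (1 + depol_f / 3))
}

#' Molecular volume scattering at 180 degrees
#'
#' beta_m(pi) = b_w p_m(pi), the Brillouin-channel backscatter amplitude used
#' to calibrate the particulate 180-degree scattering from the combined /
#' molecular wide-FOV channel ratio.
#'
#' @param water A [pure_water_optics()] object.
#' @param depol_f Molecular phase anisotropy factor.
#' @return Volume scattering function at 180 degrees, m^-1 sr^-1.
#' @export
molecular_beta_pi <- function(water = pure_water_optics(), depol_f = 0.835) {
  water$b_w * molecular_phase(pi, depol_f)
}

#' Draw scattering angles from a phase function
#'
#' Inverse-CDF sampling of the polar scattering angle, distributed as
#' p(theta) 2 pi sin(theta). Used by the Monte Carlo engine and exposed for
#' verification. A seed is required so that every draw sequence is
#' reproducible; the caller's RNG state is restored on exit.
#'
#' @param n Number of draws.
#' @param phase Either `"molecular"` or a list `list(type = "fournier_forand",
#'   xi = ...)` / `list(type = "molecular", depol_f = ...)`.
#' @param seed Integer seed; mandatory (an unseeded draw is an error).
#' @return Vector of angles in radians.
#' @export
#' @examples
#' sample_scattering_angle(5, list(type = "fournier_forand", xi = 3.5), seed = 1)
sample_scattering_angle <- function(n, phase, seed) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("sample_scattering_angle() requires an explicit integer seed")
  }
  if (is.character(phase)) phase <- list(type = phase)
  stopifnot(n >= 1)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  u <- runif(n)
  if (identical(phase$type, "fournier_forand")) {
    ff_quantile(u, phase$xi)
  } else if (identical(phase$type, "molecular")) {
    f <- if (is.null(phase$depol_f)) 0.835 else phase$depol_f
    mol_quantile(u, f)
  } else {
    stop("unknown phase type: ", phase$type)
  }
}

# Vectorized bisection inverse of the closed-form FF CDF, in log-angle space
# (the distribution spans many decades of angle for small xi).
ff_quantile <- function(u, xi) {
  check_xi(xi)
  lo <- rep(log(1e-14), length(u))
  hi <- rep(log(pi), length(u))
  floor_f <- fournier_forand_cdf(1e-14, xi)
  u <- pmax(u, floor_f) # draws below the table floor: vanishing deflection
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    fm <- fournier_forand_cdf(exp(mid), xi)
    up <- fm < u
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  exp((lo + hi) / 2)
}

mol_quantile <- function(u, depol_f = 0.835) {
  lo <- rep(0, length(u))
  hi <- rep(pi, length(u))
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    up <- molecular_phase_cdf(mid, depol_f) < u
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  (lo + hi) / 2
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
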