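# R wrapper around the semianalytic Monte Carlo engine, plus photon noise.

#' Semianalytic Monte Carlo simulation of triple-FOV HSRL signals
#'
#' Traces photon packets through the layered water column and accumulates, at
#' every collision, an analytically estimated expected return into each
#' receiver channel (local estimation), which drastically reduces variance
#' relative to counting received photons. Channels are separated by photon
#' frequency as an ideal iodine filter would: a photon passes the molecular
#' (Brillouin) channels once its history contains at least one molecular
#' scattering, while the combined wide-FOV channel accumulates all
#' contributions. The depth bin of a contribution is half the total optical
#' path (time-of-flight convention).
#'
#' @param iop An [iop_profile()] on a uniform grid; the profile grid defines
#'   the signal bins.
#' @param config A [lidar_config()].
#' @param n_photons Photon budget, at least 1e4.
#' @param seed Integer seed; the simulation is bit-reproducible for a fixed
#'   seed and the caller's RNG state is restored on exit.
#' @param nbatch Number of photon batches used to estimate Monte Carlo
#'   standard errors.
#' @return A [signal_set()]; `meta` carries the seed, photon budget, per-bin
#'   standard errors (`mol_se`, `comb_se`), and a `coverage_warning` flag set
#'   when some requested bin received no contribution.
#' @export
simulate_mc <- function(iop, config = lidar_config(), n_photons = 1e6, seed,
                        nbatch = 32) {
  stopifnot(inherits(iop, "iop_profile"), inherits(config, "lidar_config"))
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("simulate_mc() requires an explicit integer seed")
  }
  n_photons <- as.double(n_photons)
  if (n_photons < 1e4) stop("n_photons must be at least 1e4")
  w <- profile_water(iop)
  edges <- profile_edges(iop)
  dz <- diff(edges)
  if (max(dz) - min(dz) > 1e-9) stop("iop profile must be on a uniform grid")
  if (abs(edges[1]) > 1e-9) stop("profile must start at the surface (depth 0)")
  dz <- dz[1]
  nbin <- nrow(iop)
  bp <- pmax(iop$b - w$b_w, 0)

  # per-layer Fournier-Forand parameters and sampling tables (one table per
  # unique xi value)
  m <- relative_refractive_index(iop$xi)
  ffK <- 3 * (m - 1)^2 / 4
  ffv <- (3 - iop$xi) / 2
  d180 <- 1 / ffK
  ffbcoef <- (1 - d180^ffv) / (16 * pi * (d180 - 1) * d180^ffv)
  uxi <- unique(iop$xi)
  tab_idx <- match(iop$xi, uxi) - 1L
  nfwd <- 2049L
  nbwd <- 1025L
  tab_fwd <- matrix(0, nfwd, length(uxi))
  tab_bwd <- matrix(0, nbwd, length(uxi))
  F90 <- numeric(length(uxi))
  for (k in seq_along(uxi)) {
    F90[k] <- fournier_forand_cdf(pi / 2, uxi[k])
    uf <- seq(1e-12, F90[k], length.out = nfwd)
    tab_fwd[, k] <- log(ff_quantile(uf, uxi[k]))
    ub <- seq(F90[k], 1 - 1e-12, length.out = nbwd)
    tab_bwd[, k] <- ff_quantile(ub, uxi[k])
  }

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  raw <- mc_trace(as.integer(n_photons), as.integer(nbatch), dz,
                  as.integer(nbin), config$lidar_height,
                  config$receiver_radius, config$fovs / 2,
                  iop$a, iop$b, bp, w$b_w, config$mol_depol,
                  ffK, ffv, ffbcoef, tab_fwd, tab_bwd, F90, tab_idx,
                  1e-6)

  scale <- config$system_constant / (n_photons * dz)
  tot <- rowSums(raw) * scale
  # batch-based standard errors of the bin means
  bmean <- raw * (nbatch * scale)
  se <- apply(bmean, 1, sd) / sqrt(nbatch)
  dim(tot) <- c(nbin, 4)
  dim(se) <- c(nbin, 4)
  mol <- tot[, 1:3, drop = FALSE]
  comb <- tot[, 4]
  mol_se <- se[, 1:3, drop = FALSE]
  colnames(mol_se) <- hsrl_channels()[1:3]
  coverage_warning <- any(mol[, 3] == 0) || any(comb == 0)
  if (coverage_warning) {
    warning("photon budget left some depth bins without contributions; ",
            "increase n_photons or reduce max depth")
  }
  signal_set(iop$depth, mol, comb,
             meta = list(model = "mc", seed = as.integer(seed),
                         n_photons = n_photons, nbatch = nbatch,
                         mol_se = mol_se,
                         comb_se = se[, 4],
                         coverage_warning = coverage_warning,
                         config_fovs = config$fovs))
}

#' Add photon-counting noise to a signal set
#'
#' Converts signals to expected photon counts (`scale * signal + background`),
#' draws Poisson counts, and converts back to signal units by background
#' subtraction. Negative background-subtracted counts are clipped at zero
#' (flagged in `meta$noise_clipped`).
#'
#' @param signals A [signal_set()].
#' @param scale Photons per signal unit; must be positive.
#' @param background Mean background counts per bin; must be >= 0.
#' @param seed Integer seed.
#' @return A [signal_set()] with Poisson noise applied to all channels.
#' @export
add_noise <- function(signals, scale, background = 0, seed) {
  stopifnot(inherits(signals, "signal_set"))
  if (!is.finite(scale) || scale <= 0) stop("scale must be positive")
  if (!is.finite(background) || background < 0) {
    stop("background must be >= 0")
  }
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("add_noise() requires an explicit integer seed")
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  noisy <- function(x) {
    counts <- rpois(length(x), lambda = scale * x + background)
    pmax((counts - background) / scale, 0)
  }
  mol <- apply(signals$mol, 2, noisy)
  comb <- noisy(signals$comb_wide)
  clipped <- any(mol == 0 & signals$mol > 0) || any(comb == 0 &
                                                      signals$comb_wide > 0)
  meta <- signals$meta
  meta$noise <- list(scale = scale, background = background,
                     seed = as.integer(seed))
  meta$noise_clipped <- clipped
  signal_set(signals$depths, mol, comb, meta = meta)
}
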