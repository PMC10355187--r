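# Derived products from wide-FOV channels and retrieved IOPs: diffuse
# attenuation K_d, particulate backscattering b_bp, lidar ratio R, and
# single-scattering albedo omega_0.

#' Diffuse attenuation coefficient from the wide-FOV molecular channel
#'
#' `K_d(z) = -1/2 d/dz ln(signal * (H + z)^2)`, estimated by a sliding
#' least-squares slope of the range-corrected log signal. Invariant to signal
#' scaling and to the system constant. Bins whose window contains
#' non-positive signal are returned as `NA`.
#'
#' @param signals A [signal_set()] (its `mol_wide` channel is used), or a
#'   numeric vector of wide-FOV molecular signal.
#' @param config A [lidar_config()] (for the platform height).
#' @param depths Depth bin centers; taken from `signals` when it is a
#'   [signal_set()].
#' @param window Sliding window length in bins (default 5).
#' @return K_d per bin, m^-1.
#' @export
estimate_kd <- function(signals, config = lidar_config(), depths = NULL,
                        window = 5) {
  if (inherits(signals, "signal_set")) {
    depths <- signals$depths
    sig <- signals$mol[, "mol_wide"]
  } else {
    sig <- as.numeric(signals)
    if (is.null(depths)) stop("depths must be given for a raw signal vector")
  }
  stopifnot(length(sig) == length(depths), window >= 2)
  ok <- is.finite(sig) & sig > 0
  y <- rep(NA_real_, length(sig))
  y[ok] <- log(sig[ok] * (config$lidar_height + depths[ok])^2)
  half <- floor(window / 2)
  kd <- vapply(seq_along(sig), function(i) {
    idx <- max(1, i - half):min(length(sig), i + half)
    if (any(!ok[idx]) || length(idx) < 2) return(NA_real_)
    zz <- depths[idx]; yy <- y[idx]
    -0.5 * sum((zz - mean(zz)) * (yy - mean(yy))) / sum((zz - mean(zz))^2)
  }, numeric(1))
  kd
}

#' Particulate backscattering from the combined / molecular channel ratio
#'
#' At the wide FOV both channels share the same geometry and attenuation, so
#' the particulate 180-degree volume scattering follows from the channel
#' ratio: `beta_p(pi) = beta_m(pi) (comb / mol - 1)`, with the molecular
#' amplitude `beta_m(pi)` fixed by the pure-water scattering coefficient and
#' the molecular phase function. The backscattering coefficient is then
#' `b_bp = 2 pi chi beta_p(pi)`.
#'
#' @param signals A [signal_set()] with `comb_wide` and `mol_wide`.
#' @param config A [lidar_config()].
#' @param chi Conversion factor from 180-degree scattering to the backward
#'   hemisphere integral (default 1.1).
#' @return List with `bbp` and `beta_p_180` per bin; negative ratios (noise)
#'   are clipped to zero and flagged in `clipped`.
#' @export
estimate_bbp <- function(signals, config = lidar_config(), chi = 1.1) {
  stopifnot(inherits(signals, "signal_set"), chi > 0)
  mol <- signals$mol[, "mol_wide"]
  comb <- signals$comb_wide
  beta_m <- molecular_beta_pi(config$water, config$mol_depol)
  ratio <- ifelse(mol > 0, comb / mol - 1, NA_real_)
  clipped <- any(ratio < 0, na.rm = TRUE)
  beta_p <- pmax(ratio, 0) * beta_m
  list(bbp = 2 * pi * chi * beta_p, beta_p_180 = beta_p, clipped = clipped)
}

#' Lidar ratio
#'
#' `R = (K_d - K_d_pure) / beta_p(180 deg)`: the diffuse attenuation
#' excluding the pure-seawater part over the particulate volume scattering
#' function at 180 degrees.
#'
#' @param kd Diffuse attenuation coefficient(s), m^-1.
#' @param beta_p_180 Particulate volume scattering at 180 degrees,
#'   m^-1 sr^-1; non-positive values yield `NA`.
#' @param kd_pure Pure-seawater diffuse attenuation subtracted from `kd`
#'   (default `a_w + b_bw`).
#' @param water A [pure_water_optics()] used for the default `kd_pure`.
#' @return Lidar ratio in sr.
#' @export
lidar_ratio <- function(kd, beta_p_180, kd_pure = NULL,
                        water = pure_water_optics()) {
  if (is.null(kd_pure)) kd_pure <- water$a_w + water$b_bw
  out <- (kd - kd_pure) / beta_p_180
  out[!is.finite(beta_p_180) | beta_p_180 <= 0] <- NA_real_
  out
}

#' Particulate single-scattering albedo
#'
#' `omega_0 = (b - b_w) / ((a - a_w) + (b - b_w))`: the particulate
#' scattering coefficient over the particulate beam attenuation (pure
#' seawater excluded).
#'
#' @param a Total absorption, m^-1 (>= a_w).
#' @param b Total scattering, m^-1 (> b_w for a defined ratio).
#' @param water A [pure_water_optics()].
#' @return omega_0, dimensionless in (0, 1]; `NA` where the particulate beam
#'   attenuation is non-positive.
#' @export
#' @examples
#' single_scattering_albedo(0.11, 0.75) # ~0.9166
single_scattering_albedo <- function(a, b, water = pure_water_optics()) {
  ap <- a - water$a_w
  bp <- b - water$b_w
  den <- ap + bp
  out <- bp / den
  out[!is.finite(den) | den <= 0] <- NA_real_
  out
}

#' Spectral conversion of the particulate backscattering coefficient
#'
#' `b_bp(lambda) = b_bp(lambda0) * lambda0 / lambda`.
#'
#' @param bbp_ref Backscattering at the reference wavelength, m^-1.
#' @param lambda_ref Reference wavelength, nm.
#' @param lambda_out Output wavelength, nm.
#' @return Converted backscattering coefficient, m^-1.
#' @export
#' @examples
#' bbp_wavelength_convert(0.00522, 510, 532)
bbp_wavelength_convert <- function(bbp_ref, lambda_ref, lambda_out) {
  stopifnot(all(lambda_ref > 0), all(lambda_out > 0))
  bbp_ref * lambda_ref / lambda_out
}

#' Derived-product table from signals (and optionally retrieved IOPs)
#'
#' @param signals A [signal_set()].
#' @param config A [lidar_config()].
#' @param retrieved Optional retrieved [iop_profile()] used for the
#'   single-scattering albedo.
#' @param chi Conversion factor for [estimate_bbp()].
#' @param window Window for [estimate_kd()].
#' @return Data frame with depth, kd, bbp, beta_p_180, lidar_ratio, and
#'   (when `retrieved` is given) omega0.
#' @export
derive_products <- function(signals, config = lidar_config(),
                            retrieved = NULL, chi = 1.1, window = 5) {
  stopifnot(inherits(signals, "signal_set"))
  kd <- estimate_kd(signals, config, window = window)
  bb <- estimate_bbp(signals, config, chi = chi)
  out <- data.frame(depth = signals$depths, kd = kd, bbp = bb$bbp,
                    beta_p_180 = bb$beta_p_180,
                    lidar_ratio = lidar_ratio(kd, bb$beta_p_180,
                                              water = config$water))
  if (!is.null(retrieved)) {
    stopifnot(inherits(retrieved, "iop_profile"))
    idx <- match(round(out$depth, 9), round(retrieved$depth, 9))
    out$omega0 <- ifelse(is.na(idx), NA_real_,
                         single_scattering_albedo(retrieved$a[idx],
                                                  retrieved$b[idx],
                                                  profile_water(retrieved)))
  }
  out
}
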