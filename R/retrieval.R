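# Iterative triple-FOV inversion: recover (a, b, xi) profiles from the three
# molecular channels by Gauss-Newton minimization of the relative signal
# mismatch, using the analytic forward model and its finite-difference
# sensitivity.

state_bounds <- function(water) {
  list(a = c(water$a_w, 2), b = c(water$b_w, 5), xi = c(3.02, 5))
}

#' Root-mean-square relative difference
#'
#' `RMSRD = 100 * sqrt(mean((x / ref - 1)^2))`, the mismatch and accuracy
#' metric used throughout the retrieval (in percent).
#'
#' @param x Simulated or retrieved values.
#' @param ref Reference values (measured or true); must be nonzero.
#' @return RMSRD in percent.
#' @export
#' @examples
#' rmsrd(c(0.9, 1.1), c(1, 1)) # 10
rmsrd <- function(x, ref) {
  if (length(x) != length(ref) || length(x) < 1) {
    stop("x and ref must have equal positive length")
  }
  if (any(!is.finite(ref)) || any(ref == 0)) {
    stop("reference values must be finite and nonzero")
  }
  100 * sqrt(mean((x / ref - 1)^2))
}

#' Parameter-recovery RMSRD between two IOP profiles
#'
#' @param retrieved,truth [iop_profile()] objects; compared on the common
#'   depth range (the retrieved grid must be a subset of the truth grid).
#' @return List with elements `a`, `b`, `xi` (RMSRD in percent).
#' @export
rmsrd_profiles <- function(retrieved, truth) {
  stopifnot(inherits(retrieved, "iop_profile"), inherits(truth, "iop_profile"))
  idx <- match(round(retrieved$depth, 9), round(truth$depth, 9))
  if (any(is.na(idx))) stop("retrieved depths must be a subset of truth depths")
  list(a = rmsrd(retrieved$a, truth$a[idx]),
       b = rmsrd(retrieved$b, truth$b[idx]),
       xi = rmsrd(retrieved$xi, truth$xi[idx]))
}

# Centered windowed least-squares slope of y(z); window shrinks at the ends.
windowed_slope <- function(z, y, window = 5) {
  n <- length(z)
  half <- floor(window / 2)
  vapply(seq_len(n), function(i) {
    idx <- max(1, i - half):min(n, i + half)
    if (length(idx) < 2) return(NA_real_)
    zz <- z[idx]; yy <- y[idx]
    sum((zz - mean(zz)) * (yy - mean(yy))) / sum((zz - mean(zz))^2)
  }, numeric(1))
}

# Bins usable for retrieval: all channels positive, down to where the
# narrow-FOV molecular signal falls below max/dynamic_range.
usable_bins <- function(measured, dynamic_range = 1e3, min_bins = 5) {
  mn <- measured$mol[, "mol_narrow"]
  pos <- rowSums(measured$mol <= 0) == 0
  keep <- pos & (mn >= max(mn[pos]) / dynamic_range)
  last <- which(!keep)[1]
  n_use <- if (is.na(last)) length(mn) else last - 1L
  if (n_use < min_bins) {
    stop("fewer than ", min_bins, " usable bins per channel")
  }
  seq_len(n_use)
}

truncate_signals <- function(measured, idx) {
  signal_set(measured$depths[idx], measured$mol[idx, , drop = FALSE],
             measured$comb_wide[idx], meta = measured$meta)
}

#' First-guess IOP profile from measured signals
#'
#' The initial absorption is the lidar attenuation coefficient of the
#' range-corrected wide-FOV molecular channel (half its negative log-slope,
#' which approximates the diffuse attenuation); the narrow-FOV attenuation
#' approximates the beam attenuation c = a + b, so the default initial
#' scattering is `K_narrow - a0` floored at the pure-water value
#' (`literal_b = TRUE` restores the literal reading `b0 = K_narrow`). The PSD
#' slope starts at a constant mid-range coastal value.
#'
#' @param measured A [signal_set()] with all three molecular channels.
#' @param config A [lidar_config()].
#' @param xi0 Initial PSD slope (default 3.5).
#' @param window Bins in the sliding slope window.
#' @param literal_b If `TRUE`, initialize b directly with the narrow-FOV
#'   attenuation coefficient.
#' @param dynamic_range Narrow-channel dynamic range defining usable depth.
#' @return An [iop_profile()] on the usable depth grid.
#' @export
initialize_state <- function(measured, config = lidar_config(), xi0 = 3.5,
                             window = 5, literal_b = FALSE,
                             dynamic_range = 1e3) {
  stopifnot(inherits(measured, "signal_set"), inherits(config, "lidar_config"))
  idx <- usable_bins(measured, dynamic_range, min_bins = 3)
  meas <- truncate_signals(measured, idx)
  z <- meas$depths
  w <- config$water
  bounds <- state_bounds(w)
  rc <- function(chan) log(meas$mol[, chan] * (config$lidar_height + z)^2)
  k_wide <- -windowed_slope(z, rc("mol_wide"), window) / 2
  k_narrow <- -windowed_slope(z, rc("mol_narrow"), window) / 2
  if (any(k_wide <= 0, na.rm = TRUE)) {
    warning("non-decaying wide-FOV signal; clipping initial absorption ",
            "to the physical floor")
  }
  a0 <- pmin(pmax(k_wide, bounds$a[1]), bounds$a[2])
  b_raw <- if (literal_b) k_narrow else k_narrow - a0
  b0 <- pmin(pmax(b_raw, bounds$b[1]), bounds$b[2])
  iop_profile(z, a0, b0, rep(xi0, length(z)), water = w)
}

# Forward signals restacked as one vector (channels x bins, channel-major).
stack_mol <- function(signals) as.vector(signals$mol)

# Physics-consistent warm start: split the three channel attenuation
# coefficients into absorption and scattering with the quasi-single-
# scattering retention model evaluated at xi0. Per bin, the channel
# attenuation is modelled as K_ch = A + b_p (1 - F_xi0(theta_ch (H+z)/(z/2)))
# with A = a + b_w, and (A, b_p) solved by least squares over the three
# channels. The default starting slope is the median of the coastal xi range
# the scenario module emulates.
warm_start_state <- function(measured, config, xi0 = 3.3, window = 5,
                             dynamic_range = 1e3) {
  idx <- usable_bins(measured, dynamic_range, min_bins = 3)
  meas <- truncate_signals(measured, idx)
  z <- meas$depths
  w <- config$water
  bounds <- state_bounds(w)
  H <- config$lidar_height
  k <- sapply(1:3, function(ch) {
    -windowed_slope(z, log(meas$mol[, ch] * (H + z)^2), window) / 2
  })
  a0 <- b0 <- numeric(length(z))
  for (i in seq_along(z)) {
    cuts <- pmin(config$fovs / 2 * (H + z[i]) / (z[i] / 2), pi / 2)
    loss <- 1 - fournier_forand_cdf(cuts, xi0)
    fit <- tryCatch(stats::lm.fit(cbind(1, loss), k[i, ])$coefficients,
                    error = function(e) c(NA, NA))
    if (any(!is.finite(fit))) fit <- c(k[i, 3], 0)
    # the narrow-FOV attenuation bounds the particulate scattering estimate
    b0[i] <- min(max(fit[2], 0), 1.5 * max(k[i, 1], 0.01))
    a0[i] <- fit[1] - w$b_w
  }
  # the iteration needs only a smooth, roughly scaled starting profile
  krm <- if (length(a0) >= 5) 5 else if (length(a0) >= 3) 3 else 1
  a0 <- stats::runmed(a0, k = krm)
  b0 <- stats::runmed(b0, k = krm)
  a0 <- pmin(pmax(a0, bounds$a[1]), bounds$a[2])
  b0 <- pmin(pmax(b0 + w$b_w, bounds$b[1]), bounds$b[2])
  iop_profile(z, a0, b0, rep(xi0, length(z)), water = w)
}

# Relative sensitivity matrix by central finite differences: rows are the
# three molecular channels stacked over depth bins, columns the parameters
# (a then b then xi) stacked over depth bins.
relative_jacobian <- function(iop, config, step = 0.05,
                              forward = forward_analytic, nsub = 2) {
  w <- profile_water(iop)
  bounds <- state_bounds(w)
  n <- nrow(iop)
  base <- stack_mol(forward(iop, config, nsub = nsub))
  J <- matrix(0, 3 * n, 3 * n)
  pars <- c("a", "b", "xi")
  for (p in 1:3) {
    bb <- bounds[[pars[p]]]
    for (j in seq_len(n)) {
      x <- iop[[pars[p]]][j]
      hi <- min(x * (1 + step), bb[2])
      lo <- max(x * (1 - step), bb[1])
      if (hi - lo < 1e-12) next
      up <- iop; up[[pars[p]]][j] <- hi
      dn <- iop; dn[[pars[p]]][j] <- lo
      dB <- stack_mol(forward(up, config, nsub = nsub)) -
        stack_mol(forward(dn, config, nsub = nsub))
      J[, (p - 1) * n + j] <- (dB / base) / ((hi - lo) / x)
    }
  }
  J
}

#' Triple-FOV signal sensitivity matrix
#'
#' Relative response of the three molecular channels to relative
#' perturbations of (a, b, xi) per depth bin, computed by central finite
#' differences of the analytic forward model. Because the lidar signal at a
#' given depth depends only on the water above it, the matrix is
#' block-lower-triangular in depth: entries coupling a signal bin to
#' parameters of strictly deeper bins are exactly zero.
#'
#' @param iop An [iop_profile()] (the linearization point).
#' @param config A [lidar_config()].
#' @param step Relative perturbation, in (0, 0.1].
#' @param forward Forward model function (deterministic).
#' @return A `3n x 3n` matrix of class `hsrl_sensitivity` with attributes
#'   `channels`, `params`, and `depths`.
#' @export
compute_sensitivity <- function(iop, config = lidar_config(), step = 0.05,
                                forward = forward_analytic) {
  stopifnot(inherits(iop, "iop_profile"), step > 0, step <= 0.1)
  J <- relative_jacobian(iop, config, step = step, forward = forward)
  structure(J, class = c("hsrl_sensitivity", "matrix", "array"),
            channels = hsrl_channels()[1:3], params = c("a", "b", "xi"),
            depths = iop$depth,
            condition = kappa(J, exact = FALSE))
}

#' Iterative triple-FOV retrieval of (a, b, xi) profiles
#'
#' Gauss-Newton iteration on the relative mismatch between measured and
#' simulated molecular signals at the three fields of view, solved
#' simultaneously over all depth bins. Each step solves
#' `S (dX/X) = (B_M - B_S)/B_M` for the relative parameter update with
#' Levenberg-Marquardt damping (the damping factor is raised until a step
#' reduces the pooled RMSRD and relaxed after every accepted step), caps the
#' relative update, and projects the state into physical bounds. Iteration
#' stops at `max_iter`, when three consecutive damped steps fail to reduce
#' the mismatch, or when progress stalls (improvement below `min_progress`
#' RMSRD points); `converged` reports whether the final pooled RMSRD is at
#' or below `tol`, the noise-floor threshold.
#'
#' @param measured A [signal_set()] with the three molecular channels.
#' @param config A [lidar_config()].
#' @param init Optional initial [iop_profile()]; defaults to
#'   [initialize_state()].
#' @param tol Convergence threshold on the pooled signal RMSRD, percent.
#' @param max_iter Maximum accepted iterations.
#' @param step Relative finite-difference step for the sensitivity.
#' @param min_progress Stop once an accepted step improves pooled RMSRD by
#'   less than this many points.
#' @param dynamic_range Narrow-channel dynamic range defining usable depth.
#' @param smoothness Named vector of curvature-penalty weights for the three
#'   log-parameter profiles. The triple-FOV signals constrain a smooth
#'   (a, b, xi) profile well but leave nearly signal-neutral bin-to-bin
#'   wiggle modes (a larger b with a smaller xi, redistributed vertically,
#'   changes the signals by well under a percent); the second-difference
#'   penalty suppresses those modes without biasing homogeneous or linearly
#'   varying profiles. Set to zero to disable.
#' @param model_error Relative forward-model accuracy allowance added in
#'   quadrature to the per-bin measurement noise when weighting residuals.
#' @param forward Forward model used for simulation and sensitivities.
#' @return A list of class `hsrl_retrieval`: `iop` (retrieved profile),
#'   `n_iterations`, `rmsrd_final` (pooled), `rmsrd_by_fov`, `converged`,
#'   `trajectory` (per-iteration diagnostics; the minimized weighted cost is
#'   strictly decreasing over accepted steps), `flags`.
#' @export
iterate_retrieval <- function(measured, config = lidar_config(), init = NULL,
                              tol = 10, max_iter = 40, step = 0.05,
                              min_progress = 0.05, dynamic_range = 1e3,
                              smoothness = c(a = 2, b = 2, xi = 6),
                              model_error = 0.005,
                              forward = forward_analytic) {
  stopifnot(inherits(measured, "signal_set"))
  idx <- usable_bins(measured, dynamic_range, min_bins = 3)
  meas <- truncate_signals(measured, idx)
  if (is.null(init)) {
    init <- warm_start_state(measured, config, dynamic_range = dynamic_range)
  }
  stopifnot(inherits(init, "iop_profile"))
  if (nrow(init) < length(idx)) {
    idx <- idx[seq_len(nrow(init))]
    meas <- truncate_signals(measured, idx)
  }
  state <- init[seq_along(idx), , drop = FALSE]
  class(state) <- c("iop_profile", "data.frame")
  attr(state, "water") <- profile_water(init)
  w <- profile_water(state)
  bounds <- state_bounds(w)
  n <- nrow(state)
  bm <- stack_mol(meas)

  # inverse-variance weights for the relative residuals, from the Monte
  # Carlo per-bin standard errors when the measurement carries them; noisy
  # deep bins otherwise steer the fit along weakly constrained directions.
  # The forward-model accuracy allowance (model_error) floors the weights so
  # that low-noise bins are not trusted beyond the surrogate's own fidelity.
  wvec <- rep(1, 3 * n)
  if (!is.null(meas$meta$mol_se)) {
    se_rel <- as.vector(meas$meta$mol_se[idx, , drop = FALSE]) / bm
    se_rel <- pmin(sqrt(pmax(se_rel, 0)^2 + model_error^2), 1)
    wvec <- 1 / se_rel
    wvec <- wvec / sqrt(mean(wvec^2))
  }

  # curvature penalty operator on the stacked log-parameter profiles
  sm <- rep(0, 3)
  if (!is.null(smoothness)) {
    nm <- names(smoothness)
    sm <- if (is.null(nm)) rep_len(smoothness, 3) else
      c(smoothness[["a"]], smoothness[["b"]], smoothness[["xi"]])
  }
  P <- NULL
  if (n >= 3 && any(sm > 0)) {
    # curvature rows plus half-weight slope rows: the weakly constrained
    # modes are smooth tilts of b compensated by opposite tilts of xi
    L2 <- matrix(0, n - 2, n)
    for (i in seq_len(n - 2)) L2[i, i:(i + 2)] <- c(1, -2, 1)
    L1 <- matrix(0, n - 1, n)
    for (i in seq_len(n - 1)) L1[i, i:(i + 1)] <- c(1, -1)
    nr <- (n - 2) + (n - 1)
    P <- matrix(0, 3 * nr, 3 * n)
    for (p in 1:3) {
      P[(p - 1) * nr + seq_len(n - 2), (p - 1) * n + seq_len(n)] <-
        sm[p] * L2
      P[(p - 1) * nr + (n - 2) + seq_len(n - 1),
        (p - 1) * n + seq_len(n)] <- 0.5 * sm[p] * L1
    }
  }
  logx <- function(iop) log(c(iop$a, iop$b, iop$xi))

  pooled <- function(iop) {
    bs <- stack_mol(forward(iop, config))
    r <- (bm - bs) / bm
    pen <- if (is.null(P)) 0 else sum((P %*% logx(iop))^2)
    list(r = r, rmsrd = 100 * sqrt(mean(r^2)),
         cost = sum((wvec * r)^2) + pen,
         by_fov = 100 * sqrt(colMeans(matrix(r^2, ncol = 3))))
  }
  clipped <- function(iop) {
    iop$a <- pmin(pmax(iop$a, bounds$a[1]), bounds$a[2])
    iop$b <- pmin(pmax(iop$b, bounds$b[1]), bounds$b[2])
    iop$xi <- pmin(pmax(iop$xi, bounds$xi[1]), bounds$xi[2])
    iop
  }

  state <- clipped(state)
  cur <- pooled(state)
  traj <- data.frame(iteration = 0L, rmsrd = cur$rmsrd, cost = cur$cost,
                     lambda = NA_real_, max_rel_step = NA_real_)
  flags <- character(0)
  n_iter <- 0L
  fails <- 0L

  mu <- 1e-3  # Levenberg-Marquardt damping
  while (n_iter < max_iter && cur$rmsrd > 0.01) {
    prev_cost <- cur$cost
    J <- relative_jacobian(state, config, step = step, forward = forward)
    Jw <- wvec * J
    g <- crossprod(Jw)
    rhs <- crossprod(Jw, wvec * cur$r)
    if (!is.null(P)) {
      g <- g + crossprod(P)
      rhs <- rhs - crossprod(P, P %*% logx(state))
    }
    dscale <- pmax(diag(g), max(diag(g)) * 1e-12)
    if (min(diag(g)) < max(diag(g)) * 1e-14) flags <- union(flags, "regularized")

    accepted <- FALSE
    for (try_k in 1:8) {
      delta <- tryCatch(
        as.vector(solve(g + mu * diag(dscale, nrow(g)), rhs)),
        error = function(e) NULL)
      if (!is.null(delta)) {
        # cap the raw relative step to keep the update in the trust region
        delta <- pmin(pmax(delta, -0.9), 4)
        cand <- state
        cand$a <- state$a * (1 + delta[seq_len(n)])
        cand$b <- state$b * (1 + delta[n + seq_len(n)])
        cand$xi <- state$xi * (1 + delta[2 * n + seq_len(n)])
        cand <- clipped(cand)
        new <- pooled(cand)
        # monotone progress is in the minimized objective (the weighted,
        # penalized cost); the unweighted signal RMSRD may transiently rise
        # while noisy deep bins are traded against well-measured ones
        if (new$cost < cur$cost) {
          state <- cand
          cur <- new
          n_iter <- n_iter + 1L
          traj <- rbind(traj,
                        data.frame(iteration = n_iter, rmsrd = cur$rmsrd,
                                   cost = cur$cost, lambda = mu,
                                   max_rel_step = max(abs(delta))))
          accepted <- TRUE
          fails <- 0L
          mu <- max(mu / 3, 1e-10)
          break
        }
      }
      mu <- mu * 10
    }
    if (!accepted) {
      fails <- fails + 1L
      if (fails >= 3) break
    } else if (prev_cost - cur$cost < 1e-3 * prev_cost &&
               abs(traj$rmsrd[nrow(traj) - 1] - cur$rmsrd) < min_progress) {
      break  # both the weighted cost and the signal mismatch have stalled
    }
  }

  structure(list(iop = state, n_iterations = n_iter,
                 rmsrd_final = cur$rmsrd,
                 rmsrd_by_fov = stats::setNames(cur$by_fov,
                                                hsrl_channels()[1:3]),
                 converged = cur$rmsrd <= tol,
                 trajectory = traj, flags = flags),
            class = "hsrl_retrieval")
}

#' @export
print.hsrl_retrieval <- function(x, ...) {
  cat(sprintf(
    "Triple-FOV retrieval: %d iterations, pooled signal RMSRD %.2f%% (%s)\n",
    x$n_iterations, x$rmsrd_final,
    if (x$converged) "converged" else "not converged"))
  invisible(x)
}
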