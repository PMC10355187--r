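# Synthetic coastal-to-offshore water scenarios (L1-L5) and ensembles.

# Characteristic surface values per region, nearshore (L1) to offshore (L5):
# turbidity decreases while the PSD slope xi increases.
scenario_presets <- function() {
  list(
    L1 = list(a = 0.110, b = 0.75, xi = 3.15),
    L2 = list(a = 0.085, b = 0.55, xi = 3.35),
    L3 = list(a = 0.078, b = 0.40, xi = 3.35),
    L4 = list(a = 0.080, b = 0.45, xi = 3.30),
    L5 = list(a = 0.047, b = 0.25, xi = 3.42)
  )
}

#' Water scenario specification
#'
#' Describes a synthetic water body: either one of the named presets L1-L5
#' (characteristic nearshore-to-offshore coastal waters) or custom surface
#' values, optionally with layered depth structure. The L4 preset supports a
#' stratified variant with a clearer 5 m surface layer emulating an intrusion
#' of offshore water above more turbid nearshore water.
#'
#' @param name Preset name ("L1".."L5") or "custom".
#' @param a,b,xi Surface values; taken from the preset when `name` is a
#'   preset and the value is missing.
#' @param depth_max Profile depth, m.
#' @param stratified If `TRUE`, place a clearer surface layer (top 5 m with
#'   `a`, `b` scaled by 0.75 towards the pure-water floor and `xi + 0.05`).
#' @param gradients Optional list `list(breaks=, a=, b=, xi=)` giving a
#'   piecewise-constant layered structure: `breaks` are the layer bottom
#'   depths (last must be >= depth_max) and `a`, `b`, `xi` the per-layer
#'   values. Overrides `stratified`.
#' @param noise Optional photon-budget scale passed to fixtures.
#' @param seed Default seed for fixtures built from this spec.
#' @return An object of class `scenario_spec`.
#' @export
#' @examples
#' scenario_spec("L1")
#' scenario_spec("custom", a = 0.06, b = 0.3, xi = 3.4)
scenario_spec <- function(name = "custom", a = NULL, b = NULL, xi = NULL,
                          depth_max = 30, stratified = FALSE,
                          gradients = NULL, noise = NULL, seed = 1L) {
  presets <- scenario_presets()
  if (name %in% names(presets)) {
    p <- presets[[name]]
    if (is.null(a)) a <- p$a
    if (is.null(b)) b <- p$b
    if (is.null(xi)) xi <- p$xi
  } else if (!identical(name, "custom")) {
    stop("unknown scenario name: ", name, " (use L1..L5 or \"custom\")")
  }
  if (is.null(a) || is.null(b) || is.null(xi)) {
    stop("custom scenarios require a, b, and xi")
  }
  w <- pure_water_optics()
  if (a < w$a_w || a > 2 || b < w$b_w || b > 5 || xi <= 3 || xi > 5) {
    stop("scenario values outside physical bounds [a_w,2] x [b_w,5] x (3,5]")
  }
  stopifnot(depth_max > 1)
  structure(list(name = name, a = a, b = b, xi = xi, depth_max = depth_max,
                 stratified = isTRUE(stratified), gradients = gradients,
                 noise = noise, seed = seed),
            class = "scenario_spec")
}

#' Build an IOP profile from a scenario specification
#'
#' @param spec A [scenario_spec()].
#' @param bin_size Depth resolution, m.
#' @param water A [pure_water_optics()] object.
#' @return An [iop_profile()], homogeneous unless the spec is stratified or
#'   carries explicit gradients.
#' @export
#' @examples
#' make_profile(scenario_spec("L1"))
make_profile <- function(spec, bin_size = 1, water = pure_water_optics()) {
  stopifnot(inherits(spec, "scenario_spec"), bin_size > 0)
  nbin <- ceiling(spec$depth_max / bin_size)
  depths <- (seq_len(nbin) - 0.5) * bin_size
  a <- rep(spec$a, nbin)
  b <- rep(spec$b, nbin)
  xi <- rep(spec$xi, nbin)
  if (!is.null(spec$gradients)) {
    g <- spec$gradients
    stopifnot(!is.null(g$breaks), length(g$a) == length(g$breaks),
              length(g$b) == length(g$breaks),
              length(g$xi) == length(g$breaks))
    if (max(g$breaks) < spec$depth_max) {
      stop("gradients$breaks must reach depth_max")
    }
    lay <- findInterval(depths, c(0, g$breaks), left.open = TRUE,
                        rightmost.closed = TRUE)
    lay <- pmin(pmax(lay, 1L), length(g$breaks))
    a <- g$a[lay]; b <- g$b[lay]; xi <- g$xi[lay]
  } else if (spec$stratified) {
    top <- depths <= 5
    a[top] <- water$a_w + 0.75 * (spec$a - water$a_w)
    b[top] <- water$b_w + 0.75 * (spec$b - water$b_w)
    xi[top] <- pmin(spec$xi + 0.05, 5)
  }
  iop_profile(depths, a, b, xi, water = water)
}

#' Latin-hypercube ensemble of water profiles
#'
#' Draws `n` profiles whose surface values span the coastal parameter box by
#' Latin-hypercube sampling; a fixed fraction of members receives the
#' stratified (clearer surface layer) structure so that the ensemble contains
#' both homogeneous and vertically structured waters.
#'
#' @param n Number of profiles, >= 1.
#' @param ranges List with elements `a`, `b`, `xi` giving `c(min, max)`
#'   boxes; the default spans the observed coastal range.
#' @param seed Integer seed.
#' @param depth_max Profile depth, m.
#' @param bin_size Depth resolution, m.
#' @param stratified_fraction Fraction of members (every k-th) that get a
#'   stratified surface layer.
#' @return List of [iop_profile()] objects.
#' @export
make_ensemble <- function(n = 20,
                          ranges = list(a = c(0.047, 0.110),
                                        b = c(0.25, 0.75),
                                        xi = c(3.15, 3.42)),
                          seed = 1L, depth_max = 15, bin_size = 1,
                          stratified_fraction = 0.2) {
  stopifnot(n >= 1)
  for (nm in c("a", "b", "xi")) {
    r <- ranges[[nm]]
    if (is.null(r) || length(r) != 2 || diff(r) <= 0) {
      stop("ranges$", nm, " must be c(min, max) with min < max")
    }
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  u <- lhs::randomLHS(n, 3)
  every <- if (stratified_fraction > 0) max(1L, round(1 / stratified_fraction))
           else Inf
  w <- pure_water_optics()
  lapply(seq_len(n), function(i) {
    a <- ranges$a[1] + u[i, 1] * diff(ranges$a)
    b <- ranges$b[1] + u[i, 2] * diff(ranges$b)
    # profile depth covers the usable narrow-channel range (three decades of
    # two-way attenuation at the effective narrow-FOV rate) with a margin
    z_use <- log(1e3) / (2 * (a + 0.45 * (b - w$b_w)))
    spec <- scenario_spec("custom", a = a, b = b,
                          xi = ranges$xi[1] + u[i, 3] * diff(ranges$xi),
                          depth_max = min(depth_max,
                                          max(6, ceiling(z_use) + 1)),
                          stratified = (i %% every) == 0)
    make_profile(spec, bin_size = bin_size)
  })
}

#' Build a truth + simulated-signal fixture in one call
#'
#' @param spec A [scenario_spec()].
#' @param config A [lidar_config()].
#' @param n_photons Monte Carlo photon budget.
#' @param seed Integer seed (defaults to the spec seed).
#' @param noise Optional list `list(scale=, background=)` applied with
#'   [add_noise()] after the Monte Carlo simulation.
#' @return List with elements `truth` (the [iop_profile()]) and `signals`
#'   (the simulated [signal_set()]).
#' @export
make_fixture <- function(spec, config = lidar_config(), n_photons = 1e6,
                         seed = spec$seed, noise = spec$noise) {
  stopifnot(inherits(spec, "scenario_spec"))
  truth <- make_profile(spec, bin_size = config$bin_size,
                        water = config$water)
  signals <- simulate_mc(truth, config, n_photons = n_photons, seed = seed)
  if (!is.null(noise)) {
    bg <- if (is.null(noise$background)) 0 else noise$background
    signals <- add_noise(signals, scale = noise$scale, background = bg,
                         seed = seed + 1L)
  }
  list(truth = truth, signals = signals)
}
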