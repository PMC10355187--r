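# Depth-gridded inherent optical property (IOP) state: a(z), b(z), xi(z).

#' Depth-gridded inherent optical property profile
#'
#' The state vector of the retrieval: total absorption `a`, total scattering
#' `b`, and PSD slope `xi` on a depth grid (bin centers, positive-down meters
#' from the air-water interface). Totals include the pure-seawater part, so
#' `a >= a_w`, `b >= b_w`.
#'
#' @param depths Depth bin centers, m; strictly increasing, starting >= 0.
#' @param a Absorption coefficient per bin, m^-1.
#' @param b Total scattering coefficient per bin, m^-1.
#' @param xi PSD slope per bin, in (3, 5].
#' @param water A [pure_water_optics()] object giving the pure-seawater part.
#' @return An object of class `iop_profile` (a data frame with columns
#'   `depth`, `a`, `b`, `xi` and a `water` attribute).
#' @export
#' @examples
#' iop_profile(depths = seq(0.5, 9.5), a = rep(0.08, 10),
#'             b = rep(0.4, 10), xi = rep(3.35, 10))
iop_profile <- function(depths, a, b, xi, water = pure_water_optics()) {
  n <- length(depths)
  if (n < 1 || length(a) != n || length(b) != n || length(xi) != n) {
    stop("depths, a, b, xi must have equal positive length")
  }
  if (any(!is.finite(depths)) || any(depths < 0) || any(diff(depths) <= 0)) {
    stop("depths must be finite, start >= 0, and be strictly increasing")
  }
  stopifnot(inherits(water, "pure_water_optics"))
  if (any(!is.finite(a)) || any(a < water$a_w - 1e-12)) {
    stop("absorption a must be >= pure-water a_w = ", water$a_w)
  }
  if (any(!is.finite(b)) || any(b < water$b_w - 1e-12)) {
    stop("scattering b must be >= pure-water b_w = ", water$b_w)
  }
  check_xi(xi)
  out <- data.frame(depth = depths, a = a, b = b, xi = xi)
  attr(out, "water") <- water
  class(out) <- c("iop_profile", "data.frame")
  out
}

#' @export
print.iop_profile <- function(x, ...) {
  cat(sprintf("IOP profile: %d bins, %g-%g m\n", nrow(x),
              min(x$depth), max(x$depth)))
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

profile_water <- function(iop) {
  w <- attr(iop, "water")
  if (is.null(w)) pure_water_optics() else w
}

#' Total and particulate backscattering of a profile
#'
#' Computes the particulate backscattering coefficient
#' `b_bp = BF(xi) * (b - b_w)` and total `b_b = b_bp + b_bw` per bin.
#'
#' @param iop An [iop_profile()].
#' @return Data frame with columns `depth`, `b_bp`, `b_b`.
#' @export
profile_backscatter <- function(iop) {
  stopifnot(inherits(iop, "iop_profile"))
  w <- profile_water(iop)
  b_bp <- backscatter_fraction(iop$xi) * (iop$b - w$b_w)
  data.frame(depth = iop$depth, b_bp = b_bp, b_b = b_bp + w$b_bw)
}

# Uniform layer geometry helpers: layer i spans (edges[i], edges[i+1]].
profile_edges <- function(iop) {
  d <- iop$depth
  if (length(d) == 1) return(c(max(0, d - 0.5), d + 0.5))
  mid <- (d[-1] + d[-length(d)]) / 2
  c(max(0, d[1] - (mid[1] - d[1])), mid,
    d[length(d)] + (d[length(d)] - mid[length(mid)]))
}
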