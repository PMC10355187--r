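# Range-resolved multi-channel lidar return container.

#' Range-resolved triple-FOV lidar signal set
#'
#' Holds molecular-channel returns at the three fields of view plus the
#' combined (particulate + molecular) return at the wide FOV, on a common
#' depth grid of bin centers.
#'
#' @param depths Depth bin centers, m.
#' @param mol Numeric matrix `length(depths) x 3` with columns
#'   `mol_narrow`, `mol_mid`, `mol_wide`.
#' @param comb_wide Combined wide-FOV signal per bin.
#' @param meta List of metadata (generating model, seed, photon budget,
#'   standard errors, configuration echo).
#' @return An object of class `signal_set`.
#' @export
signal_set <- function(depths, mol, comb_wide, meta = list()) {
  mol <- as.matrix(mol)
  n <- length(depths)
  if (nrow(mol) != n || ncol(mol) != 3) {
    stop("mol must be a length(depths) x 3 matrix")
  }
  if (length(comb_wide) != n) stop("comb_wide must match depths")
  if (any(!is.finite(mol)) || any(!is.finite(comb_wide))) {
    stop("signals must be finite")
  }
  if (any(mol < 0) || any(comb_wide < 0)) stop("signals must be >= 0")
  colnames(mol) <- hsrl_channels()[1:3]
  structure(list(depths = depths, mol = mol, comb_wide = comb_wide,
                 meta = meta),
            class = "signal_set")
}

#' @export
print.signal_set <- function(x, ...) {
  tag <- if (is.null(x$meta$model)) "unknown model" else x$meta$model
  cat(sprintf("Triple-FOV signal set (%s): %d bins, %g-%g m\n", tag,
              length(x$depths), min(x$depths), max(x$depths)))
  invisible(x)
}

#' Convert a signal set to a data frame
#'
#' @param x A [signal_set()].
#' @param ... Unused.
#' @return Data frame with depth and the four canonical channels.
#' @export
as.data.frame.signal_set <- function(x, ...) {
  data.frame(depth_m = x$depths,
             mol_narrow = x$mol[, "mol_narrow"],
             mol_mid = x$mol[, "mol_mid"],
             mol_wide = x$mol[, "mol_wide"],
             comb_wide = x$comb_wide)
}
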