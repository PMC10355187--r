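# Instrument geometry and channel description.

#' Lidar instrument configuration
#'
#' Geometry and channel layout of the triple-FOV HSRL: three molecular
#' (Brillouin) receiver channels at nested fields of view plus one combined
#' channel at the widest FOV. Fields of view are full angles measured in
#' water; the air-water interface is treated as flat and refraction-free, so
#' the platform height enters only through the range correction and the
#' receiver footprint.
#'
#' @param wavelength Laser wavelength, nm.
#' @param fovs Three receiver full-angle fields of view in radians, strictly
#'   increasing (defaults 0.040, 0.080, 0.200 rad).
#' @param lidar_height Platform height of the receiver above the water
#'   surface, m.
#' @param receiver_radius Effective receiver aperture radius, m.
#' @param bin_size Range (depth) resolution, m.
#' @param max_depth Maximum simulated/retrieved depth, m.
#' @param system_constant System constant C0 multiplying all channels
#'   (arbitrary signal units).
#' @param water A [pure_water_optics()] object.
#' @param mol_depol Molecular phase-function anisotropy factor `f` in
#'   p(theta) proportional to 1 + f cos^2(theta).
#' @return An object of class `lidar_config`.
#' @export
#' @examples
#' lidar_config()
lidar_config <- function(wavelength = 532,
                         fovs = c(0.040, 0.080, 0.200),
                         lidar_height = 5,
                         receiver_radius = 0.1,
                         bin_size = 1,
                         max_depth = 30,
                         system_constant = 1,
                         water = pure_water_optics(wavelength = wavelength),
                         mol_depol = 0.835) {
  if (length(fovs) != 3 || any(diff(fovs) <= 0)) {
    stop("fovs must be three strictly increasing full angles ",
         "(narrow, middle, wide)")
  }
  stopifnot(all(fovs > 0), lidar_height > 0, receiver_radius > 0,
            bin_size > 0, max_depth > bin_size, system_constant > 0,
            inherits(water, "pure_water_optics"))
  structure(list(wavelength = wavelength, fovs = fovs,
                 lidar_height = lidar_height,
                 receiver_radius = receiver_radius,
                 bin_size = bin_size, max_depth = max_depth,
                 system_constant = system_constant,
                 water = water, mol_depol = mol_depol),
            class = "lidar_config")
}

#' @export
print.lidar_config <- function(x, ...) {
  cat(sprintf("Triple-FOV HSRL configuration (%g nm)\n", x$wavelength))
  cat(sprintf("  FOVs (full angle): %s mrad\n",
              paste(format(x$fovs * 1e3), collapse = ", ")))
  cat(sprintf("  height %g m, aperture radius %g m, bins %g m to %g m\n",
              x$lidar_height, x$receiver_radius, x$bin_size, x$max_depth))
  invisible(x)
}

#' Channel names of a triple-FOV signal set
#'
#' @return Canonical channel names, narrow to wide molecular plus the
#'   combined wide-FOV channel.
#' @export
hsrl_channels <- function() c("mol_narrow", "mol_mid", "mol_wide", "comb_wide")
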