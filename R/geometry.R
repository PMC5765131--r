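# Angular unit helpers and binocular viewing geometry.

#' Arcminutes per radian
#'
#' Conversion constant between radians and arcminutes of visual angle
#' (180 / pi * 60).
#' @export
ARCMIN_PER_RAD <- 180 / pi * 60

#' Binocular viewing geometry
#'
#' Describes a symmetrically converged two-camera (two-eye) rig: the
#' interocular separation, the distance to the fixated point, the angular
#' half-width of the imaged field and the angular size of one pixel.
#' Azimuth is positive rightward, elevation positive upward, with the
#' origin at fixation (the image centre).
#'
#' @param interocular_mm Interocular separation in millimetres. Default 65,
#'   the standard adult human value.
#' @param fixation_mm Distance from the cyclopean point to the fixated
#'   point, millimetres.
#' @param field_half_width Angular half-width of the imaged field, arcmin.
#' @param pixel_pitch Angular size of one pixel, arcmin/px.
#' @return An object of class `viewing_geometry`.
#' @examples
#' geom <- viewing_geometry(fixation_mm = 1000)
#' @export
viewing_geometry <- function(interocular_mm = 65, fixation_mm = 1000,
                             field_half_width = 600, pixel_pitch = 1) {
  stopifnot(interocular_mm > 0, fixation_mm > 0,
            field_half_width > 0, pixel_pitch > 0)
  structure(list(interocular_mm = interocular_mm,
                 fixation_mm = fixation_mm,
                 field_half_width = field_half_width,
                 pixel_pitch = pixel_pitch),
            class = "viewing_geometry")
}

#' @export
print.viewing_geometry <- function(x, ...) {
  cat(sprintf(
    "viewing_geometry: I = %g mm, D = %g mm, field +/-%g arcmin @ %g arcmin/px\n",
    x$interocular_mm, x$fixation_mm, x$field_half_width, x$pixel_pitch))
  invisible(x)
}

#' Horizontal disparity of a point at a given depth
#'
#' Small-angle vergence model for symmetric convergence: a point at depth
#' `Z` straight ahead of an observer fixating at distance `D` with
#' interocular separation `I` has horizontal disparity
#' `d = I * (1/D - 1/Z)` radians. Positive disparity means the point is
#' farther than fixation (uncrossed), negative nearer (crossed); the
#' fixated point has zero disparity.
#'
#' @param depth_mm Depth(s) in millimetres; strictly positive. Vector or
#'   matrix.
#' @param geometry A [viewing_geometry()].
#' @return Disparity in arcminutes, same shape as `depth_mm`.
#' @examples
#' g <- viewing_geometry(interocular_mm = 65, fixation_mm = 1000)
#' depth_to_horizontal_disparity(2000, g)  # ~ +111.7 arcmin (far)
#' @export
depth_to_horizontal_disparity <- function(depth_mm, geometry) {
  if (any(!is.finite(depth_mm)) || any(depth_mm <= 0))
    stop("depth must be finite and strictly positive")
  d_rad <- geometry$interocular_mm *
    (1 / geometry$fixation_mm - 1 / depth_mm)
  d_rad * ARCMIN_PER_RAD
}

#' Vertical disparity field of a verged system
#'
#' For symmetric convergence with zero elevation and no cyclorotation, the
#' vertical disparity of a point grows away from both meridians with the
#' quadrant sign pattern: positive (feature higher in the LEFT image) in
#' the top-left and bottom-right quadrants, negative in the top-right and
#' bottom-left. This is modelled as the separable field
#' `v(x, y) = -gain * x * y` with `x` azimuth and `y` elevation in arcmin.
#'
#' @param azimuth Azimuth in arcmin (positive rightward); any shape.
#' @param elevation Elevation in arcmin (positive upward); same shape as
#'   `azimuth` (elementwise evaluation).
#' @param gain Dimensionless gain `gamma >= 0`; 0 gives an all-zero field.
#' @return Vertical disparity in arcmin, same shape as the inputs.
#'   Positive values mean the feature projects higher in the left image.
#' @examples
#' vertical_disparity_field(-100, 100, 1e-4)  # +1 arcmin, top-left
#' @export
vertical_disparity_field <- function(azimuth, elevation, gain) {
  stopifnot(gain >= 0)
  -gain * azimuth * elevation
}
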