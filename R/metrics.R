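# Per-component binocular measures and distribution statistics.

wrap_pi <- function(x) ((x + pi) %% (2 * pi)) - pi

#' Position disparity of a fitted binocular component
#'
#' The offset between the Gabor envelope centres fitted to the left- and
#' right-eye halves, converted to arcmin. Conventions: azimuth positive
#' rightward and elevation positive upward, so
#' `dx = (centre_x_right - centre_x_left) * res` is positive for
#' uncrossed/far-tuned components (matching the generator's geometry),
#' and `dy = (centre_y_left - centre_y_right) * res` is positive when
#' the feature is higher in the left eye. Swapping the eyes negates both.
#'
#' @param gl,gr [gabor_params()] fitted to the left and right halves.
#' @param res Sample resolution, arcmin/sample.
#' @return Named numeric `c(dx, dy)` in arcmin.
#' @export
position_disparity <- function(gl, gr, res) {
  if (is_gabor_failure(gl) || is_gabor_failure(gr))
    stop("position disparity requires two valid Gabor fits")
  c(dx = (gr$centre_x - gl$centre_x) * res,
    dy = (gl$centre_y - gr$centre_y) * res)
}

#' Phase disparity of a fitted binocular component
#'
#' The absolute difference of carrier phases, each measured relative to
#' its own envelope centre, wrapped to `[0, pi]`: 0 means the two eyes see
#' correlated structure, `pi` anti-correlated structure. When the two
#' carrier orientations are more than 90 degrees apart (as directions),
#' the right eye is first re-expressed with `theta -> theta + pi`,
#' `phi -> -phi` so the comparison is between aligned carriers.
#'
#' @param gl,gr [gabor_params()] (canonical) for the two eyes.
#' @return Phase disparity in radians, `[0, pi]`; symmetric in eye
#'   exchange.
#' @export
phase_disparity <- function(gl, gr) {
  if (is_gabor_failure(gl) || is_gabor_failure(gr))
    stop("phase disparity requires two valid Gabor fits")
  phr <- gr$phi
  if (abs(gl$theta - gr$theta) > pi / 2) phr <- -phr
  abs(wrap_pi(phr - gl$phi))
}

#' Orientation disparity of a fitted binocular component
#'
#' Absolute circular difference of the carrier orientations (which live
#' on `[0, pi)`), reported in degrees on `[0, 90]`.
#'
#' @param gl,gr [gabor_params()] (canonical) for the two eyes.
#' @return Degrees in `[0, 90]`; symmetric in eye exchange.
#' @export
orientation_disparity <- function(gl, gr) {
  if (is_gabor_failure(gl) || is_gabor_failure(gr))
    stop("orientation disparity requires two valid Gabor fits")
  d <- abs(gl$theta - gr$theta)
  min(d, pi - d) * 180 / pi
}

#' Mirror asymmetry of a distribution about its midpoint
#'
#' For a normalized histogram over `[0, pi]` with an even number of bins,
#' the asymmetry is the sum of absolute differences between the histogram
#' and its mirror about `pi/2`, divided by 2 (the maximum attainable
#' pre-division difference for a normalized distribution is 2.0). A
#' perfectly symmetric distribution scores 0; a distribution with all its
#' mass on one side of the midpoint scores 1.
#'
#' @param hist Numeric vector of bin masses (even length). If it does not
#'   sum to 1 it is normalized internally with a warning.
#' @return Asymmetry in `[0, 1]`.
#' @export
asymmetry <- function(hist) {
  if (length(hist) %% 2 != 0)
    stop("asymmetry requires an even number of bins (mirror about the midpoint)")
  s <- sum(hist)
  if (s <= 0) stop("histogram has no mass")
  if (abs(s - 1) > 1e-8) {
    warning("histogram not normalized; normalizing internally")
    hist <- hist / s
  }
  sum(abs(hist - rev(hist))) / 2
}

#' Median absolute deviation, unscaled
#'
#' `median(|x - median(x)|)` with no consistency factor (unlike
#' [stats::mad()], which scales by 1.4826 by default).
#'
#' @param values Non-empty numeric vector.
#' @return Scalar in the units of `values`.
#' @export
mad_stat <- function(values) {
  if (length(values) == 0) stop("mad of an empty vector")
  stats::median(abs(values - stats::median(values)))
}

#' Classify a component as monocular or binocular
#'
#' Binocular iff the energy ratio meets the threshold (boundary
#' inclusive). The radial analysis uses threshold 0.25 ("no more than
#' twice the energy" reading of the printed rule); the quadrant analysis
#' uses 0.5.
#'
#' @param ratio Binocular energy ratio in `[0, 1]`.
#' @param threshold Threshold in `[0, 1]`; default 0.25.
#' @return `"binocular"` or `"monocular"` (vectorized over `ratio`).
#' @export
classify_binocularity <- function(ratio, threshold = 0.25) {
  if (threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]")
  ifelse(ratio >= threshold, "binocular", "monocular")
}

#' Tidy measure table for a set of fitted components
#'
#' One row per component: energies, binocular ratio, validity, the
#' per-eye Gabor parameters, and the derived disparity measures
#' (`NA` where a fit failed). Frequency is reported as the mean of the
#' left and right fitted frequencies; `freq_arcmin = freq / res` exactly.
#'
#' @param components List of components from [fit_component()].
#' @param res Sample resolution, arcmin/sample.
#' @return A data frame.
#' @export
component_measures <- function(components, res) {
  rows <- lapply(components, function(cp) {
    ok <- isTRUE(cp$valid)
    gl <- cp$gabor_left; gr <- cp$gabor_right
    fits <- !is_gabor_failure(gl) && !is_gabor_failure(gr)
    pd <- if (fits) position_disparity(gl, gr, res) else c(dx = NA_real_, dy = NA_real_)
    data.frame(
      index = if (is.null(cp$index)) NA_integer_ else cp$index,
      left_energy = cp$left_energy, right_energy = cp$right_energy,
      binocular_ratio = cp$binocular_ratio,
      valid = ok,
      rejection = if (is.null(cp$rejection)) NA_character_ else cp$rejection,
      dx = pd[["dx"]], dy = pd[["dy"]],
      dphi = if (fits) phase_disparity(gl, gr) else NA_real_,
      dtheta = if (fits) orientation_disparity(gl, gr) else NA_real_,
      freq = if (fits) (gl$f + gr$f) / 2 else NA_real_,
      freq_arcmin = if (fits) (gl$f + gr$f) / 2 / res else NA_real_,
      f_left = if (!is_gabor_failure(gl)) gl$f else NA_real_,
      f_right = if (!is_gabor_failure(gr)) gr$f else NA_real_,
      theta_left = if (!is_gabor_failure(gl)) gl$theta else NA_real_,
      theta_right = if (!is_gabor_failure(gr)) gr$theta else NA_real_,
      phi_left = if (!is_gabor_failure(gl)) gl$phi else NA_real_,
      phi_right = if (!is_gabor_failure(gr)) gr$phi else NA_real_,
      err_left = if (!is_gabor_failure(gl)) gl$fit_error else NA_real_,
      err_right = if (!is_gabor_failure(gr)) gr$fit_error else NA_real_)
  })
  do.call(rbind, rows)
}
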