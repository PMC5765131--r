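# Synthetic verged stereo-pair generator with ground-truth disparity,
# plus low-level fixtures (Gabor patches, sparse-source sets) for testing
# the downstream stages.

#' Scene specification for the synthetic stereo generator
#'
#' A stated world for the generator: a luminance texture with a natural
#' 1/f-like amplitude spectrum, a depth map (uniform, explicit matrix, or
#' parametric ground plane) that induces the horizontal-disparity field,
#' and a separable vertical-disparity model with quadrant sign structure.
#'
#' @param depth Either a single depth in mm (fronto-parallel plane), a
#'   numeric matrix of depths (mm) on the full raster, or a
#'   [ground_plane()] object.
#' @param texture_alpha Exponent of the texture amplitude spectrum
#'   (`amplitude ~ 1/f^alpha`, so power `~ 1/f^(2*alpha)`); default 1,
#'   the classical natural-image value.
#' @param texture_cutoff Isotropic frequency cutoff of the texture,
#'   cycles/px; frequencies above it carry no energy. Default 0.45 (just
#'   below Nyquist).
#' @param vertical_gain Gain `gamma` of the vertical-disparity field
#'   `v = -gamma * azimuth * elevation` (arcmin inputs). Default 2e-5,
#'   chosen so the vertical disparities at the outer eccentricities are
#'   roughly half the size of the ground-plane horizontal disparities.
#' @param texture_model `"deadleaves"` (default; non-Gaussian, required
#'   for identifiable ICA) or `"gaussian"` — see [synth_texture()].
#' @param rng_seed Integer seed; the generator is a pure function of it.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(depth, texture_alpha = 1, texture_cutoff = 0.45,
                       vertical_gain = 2e-5, rng_seed = 1,
                       texture_model = c("deadleaves", "gaussian")) {
  stopifnot(texture_alpha >= 0, texture_cutoff > 0, vertical_gain >= 0)
  if (is.numeric(depth) && any(depth <= 0))
    stop("depth map must be strictly positive")
  structure(list(depth = depth, texture_alpha = texture_alpha,
                 texture_cutoff = texture_cutoff,
                 vertical_gain = vertical_gain,
                 rng_seed = as.integer(rng_seed),
                 texture_model = match.arg(texture_model)),
            class = "scene_spec")
}

#' Parametric ground-plane depth model
#'
#' An observer whose cyclopean eye is `eye_height_mm` above a horizontal
#' ground plane fixates a point ON the plane at (slant) distance
#' `fixation_mm` (taken from the viewing geometry at render time). A ray
#' leaving the eye at elevation `e` (arcmin, relative to the fixation
#' direction) meets the plane at slant distance
#' `Z(e) = h / sin(delta - e)` where `sin(delta) = h / D`. Depth therefore
#' increases above fixation (uncrossed/far disparities at the top of the
#' image) and decreases below it (crossed/near at the bottom); rays at or
#' above the horizon are clipped to `far_clip_mm`.
#'
#' @param eye_height_mm Eye height above the plane, mm; must not exceed
#'   the fixation distance.
#' @param far_clip_mm Depth assigned to rays that miss the plane.
#' @return An object of class `ground_plane`.
#' @export
ground_plane <- function(eye_height_mm = 1600, far_clip_mm = 20000) {
  stopifnot(eye_height_mm > 0, far_clip_mm > 0)
  structure(list(eye_height_mm = eye_height_mm, far_clip_mm = far_clip_mm),
            class = "ground_plane")
}

#' Depth of the fronto-parallel plane giving a uniform disparity
#'
#' Inverts the vergence formula: the depth `Z` such that
#' `I * (1/D - 1/Z)` equals `d0` arcmin. Useful for building scenes with
#' a single known imposed shift.
#'
#' @param d0 Target uniform horizontal disparity, arcmin.
#' @param geometry A [viewing_geometry()].
#' @return Depth in mm.
#' @export
uniform_disparity_depth <- function(d0, geometry) {
  inv <- 1 / geometry$fixation_mm -
    (d0 / ARCMIN_PER_RAD) / geometry$interocular_mm
  if (inv <= 0)
    stop("requested disparity places the plane at or beyond infinity")
  1 / inv
}

# Evaluate the scene's depth (mm) on the raster defined by the pair grid.
scene_depth_map <- function(scene, geometry, azimuth, elevation) {
  d <- scene$depth
  if (inherits(d, "ground_plane")) {
    h <- d$eye_height_mm
    D <- geometry$fixation_mm
    if (h > D) stop("eye height exceeds fixation distance")
    delta <- asin(h / D)
    e_rad <- elevation / ARCMIN_PER_RAD
    s <- sin(delta - e_rad)
    z_row <- ifelse(s > h / d$far_clip_mm, h / s, d$far_clip_mm)
    matrix(z_row, nrow = length(elevation), ncol = length(azimuth))
  } else if (is.matrix(d)) {
    stopifnot(nrow(d) == length(elevation), ncol(d) == length(azimuth))
    d
  } else {
    matrix(d, nrow = length(elevation), ncol = length(azimuth))
  }
}

#' Synthesize a natural-statistics texture
#'
#' Two texture models are available.
#'
#' `model = "deadleaves"` (default): the dead-leaves occlusion model —
#' opaque disks with a scale-invariant radius law (`p(r) ~ r^-3`) and
#' independent uniform intensities are stacked front-to-back until the
#' canvas is covered. This classical model reproduces the two defining
#' statistics of natural images at once: an approximately `1/f^2` power
#' spectrum AND the sparse, heavy-tailed edge structure that makes
#' independent components identifiable (a purely Gaussian `1/f` field
#' has no higher-order structure, so ICA cannot learn localized filters
#' from it). A light Gaussian blur (`blur_px`) band-limits the occlusion
#' edges.
#'
#' `model = "gaussian"`: spectral synthesis — complex Gaussian noise
#' shaped by `amplitude(f) = 1/max(f, 1/n)^alpha` with an isotropic
#' cutoff, inverse FFT. Gaussian by construction; useful for warping /
#' interpolation tests, useless for ICA.
#'
#' The result is standardized to mean 0, sd 1 in both cases.
#'
#' @param n Side length in pixels.
#' @param alpha Amplitude-spectrum exponent of the Gaussian model,
#'   `>= 0`.
#' @param cutoff Frequency cutoff, cycles/px (both models).
#' @param seed Integer seed; the texture is a pure function of it.
#' @param model `"deadleaves"` or `"gaussian"`.
#' @param blur_px Gaussian blur sigma in px applied to the dead-leaves
#'   canvas; default 0.8.
#' @return An `n x n` numeric matrix.
#' @export
synth_texture <- function(n, alpha = 1, cutoff = 0.45, seed = 1,
                          model = c("deadleaves", "gaussian"),
                          blur_px = 0.8) {
  stopifnot(n >= 8, alpha >= 0, cutoff > 0)
  model <- match.arg(model)
  img <- if (model == "gaussian")
    gaussian_texture(n, alpha, cutoff, seed)
  else dead_leaves_texture(n, seed, blur_px = blur_px, cutoff = cutoff)
  (img - mean(img)) / stats::sd(img)
}

gaussian_texture <- function(n, alpha, cutoff, seed) {
  f1 <- ifelse(0:(n - 1) <= n / 2, 0:(n - 1), 0:(n - 1) - n) / n
  fr <- sqrt(outer(f1^2, f1^2, "+"))
  amp <- 1 / pmax(fr, 1 / n)^alpha
  amp[fr > cutoff] <- 0
  amp[1, 1] <- 0  # zero-mean texture
  w <- withr::with_seed(seed, {
    matrix(complex(real = stats::rnorm(n * n),
                   imaginary = stats::rnorm(n * n)), n, n)
  })
  Re(stats::fft(w * amp, inverse = TRUE)) / n
}

dead_leaves_texture <- function(n, seed, r_min = 4, blur_px = 0.8,
                                cutoff = 0.45, max_disks = 400000) {
  r_max <- n / 6
  img <- withr::with_seed(seed, {
    canvas <- matrix(NA_real_, n, n)
    uncovered <- n * n
    k <- 0L
    while (uncovered > 0 && k < max_disks) {
      k <- k + 1L
      # inverse-CDF draw from p(r) ~ r^-3 on [r_min, r_max]
      u <- stats::runif(1)
      r <- 1 / sqrt((1 - u) / r_min^2 + u / r_max^2)
      cx <- stats::runif(1, 1, n); cy <- stats::runif(1, 1, n)
      val <- stats::runif(1, -1, 1)
      ri <- max(1, ceiling(cy - r)):min(n, floor(cy + r))
      ci <- max(1, ceiling(cx - r)):min(n, floor(cx + r))
      sub <- canvas[ri, ci, drop = FALSE]
      if (!anyNA(sub)) next  # fully occluded by nearer leaves
      inside <- outer((ri - cy)^2, (ci - cx)^2, "+") <= r^2
      paint <- inside & is.na(sub)
      if (any(paint)) {
        sub[paint] <- val
        canvas[ri, ci] <- sub
        uncovered <- uncovered - sum(paint)
      }
    }
    canvas[is.na(canvas)] <- 0  # background leaf
    canvas
  })
  if (blur_px > 0 || cutoff < 0.5) {
    f1 <- ifelse(0:(n - 1) <= n / 2, 0:(n - 1), 0:(n - 1) - n) / n
    fr2 <- outer(f1^2, f1^2, "+")
    h <- exp(-2 * pi^2 * blur_px^2 * fr2)
    h[fr2 > cutoff^2] <- 0
    img <- Re(stats::fft(stats::fft(img) * h, inverse = TRUE)) / n^2
  }
  img
}

# Bilinear interpolation of matrix `img` at fractional (row, col)
# positions; coordinates are clamped to the raster.
bilinear_sample <- function(img, row, col) {
  nr <- nrow(img); nc <- ncol(img)
  row <- pmin(pmax(row, 1), nr)
  col <- pmin(pmax(col, 1), nc)
  r0 <- pmin(floor(row), nr - 1); c0 <- pmin(floor(col), nc - 1)
  fr <- row - r0; fc <- col - c0
  i00 <- (c0 - 1) * nr + r0
  v <- (1 - fr) * (1 - fc) * img[i00] +
    fr * (1 - fc) * img[i00 + 1] +
    (1 - fr) * fc * img[i00 + nr] +
    fr * fc * img[i00 + nr + 1]
  if (is.matrix(row)) matrix(v, nrow(row), ncol(row)) else v
}

#' Render a verged synthetic stereo pair with ground truth
#'
#' Synthesizes a 1/f^alpha texture, computes the horizontal-disparity
#' field from the scene's depth map via [depth_to_horizontal_disparity()]
#' and the vertical field via [vertical_disparity_field()], and warps half
#' of each disparity into each eye: the left image samples the texture at
#' `(x + d/2, y - v/2)` and the right at `(x - d/2, y + v/2)`, so a
#' feature with `v > 0` sits higher in the left image and one with `d > 0`
#' (far) is displaced outward. Warping is bilinear; the returned pair
#' records the contaminated border margin so that patch sampling can avoid
#' it. Deterministic given `scene$rng_seed`.
#'
#' @param scene A [scene_spec()].
#' @param geometry A [viewing_geometry()].
#' @param warp_budget Maximum tolerated per-eye warp magnitude, arcmin;
#'   larger ground-truth disparities raise an error (prevents fold-over).
#' @return A list with elements `pair` ([stereo_pair()]), `truth`
#'   ([disparity_field()]), `texture`, `scene`, `geometry`.
#' @export
render_stereo_pair <- function(scene, geometry, warp_budget = 60) {
  pitch <- geometry$pixel_pitch
  n <- 2 * round(geometry$field_half_width / pitch) + 1
  azimuth <- (seq_len(n) - (n + 1) / 2) * pitch
  elevation <- ((n + 1) / 2 - seq_len(n)) * pitch

  tex <- synth_texture(n, scene$texture_alpha, scene$texture_cutoff,
                       seed = scene$rng_seed,
                       model = scene$texture_model %||% "deadleaves")
  z <- scene_depth_map(scene, geometry, azimuth, elevation)
  d <- depth_to_horizontal_disparity(z, geometry)
  v <- vertical_disparity_field(
    matrix(azimuth, n, n, byrow = TRUE),
    matrix(elevation, n, n), scene$vertical_gain)

  shift <- max(abs(d), abs(v)) / 2
  if (shift > warp_budget)
    stop(sprintf("ground-truth disparity (%.1f arcmin half-shift) exceeds warp budget (%g arcmin)",
                 shift, warp_budget))

  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  # left eye: sample at (x + d/2, y - v/2); elevation decreases with row
  left <- bilinear_sample(tex, rows + (v / 2) / pitch, cols + (d / 2) / pitch)
  right <- bilinear_sample(tex, rows - (v / 2) / pitch, cols - (d / 2) / pitch)

  pair <- stereo_pair(left, right, pitch, azimuth, elevation,
                      margin = shift + pitch)
  list(pair = pair, truth = disparity_field(d, v), texture = tex,
       scene = scene, geometry = geometry)
}

#' Generate a noisy Gabor patch
#'
#' Evaluates the Gabor model ([eval_gabor()]) on the integer sample grid
#' and optionally adds white Gaussian noise. Used as a fixture for the
#' fitting stage.
#'
#' @param params A [gabor_params()]; frequency must be below Nyquist
#'   (0.5 cycles/sample).
#' @param size Patch side length in samples, `>= 4`.
#' @param noise_sd Standard deviation of additive white noise (0 = none).
#' @param rng_seed Integer seed for the noise.
#' @return A `size x size` matrix, row 1 = top (positive elevation).
#' @export
make_gabor_patch <- function(params, size, noise_sd = 0, rng_seed = 1) {
  stopifnot(size >= 4)
  if (params$f >= 0.5)
    stop("carrier frequency must be below Nyquist (0.5 cycles/sample)")
  g <- gabor_grid(size)
  patch <- eval_gabor(params,
                      matrix(g$x, size, size, byrow = TRUE),
                      matrix(g$y, size, size))
  if (noise_sd > 0)
    patch <- patch + withr::with_seed(rng_seed,
      matrix(stats::rnorm(size * size, sd = noise_sd), size, size))
  patch
}

#' Generate mixed heavy-tailed sources for ICA testing
#'
#' Draws `n_sources` independent double-exponential (Laplace) source
#' signals and mixes them with a random full-rank square matrix; both the
#' mixed data and the true mixing matrix are returned, so estimated
#' unmixing matrices can be scored with [amari_index()].
#'
#' @param n_sources Number of sources.
#' @param n_samples Number of samples; should be much larger than
#'   `n_sources`.
#' @param mixing_seed,source_seed Integer seeds for the mixing matrix and
#'   the sources.
#' @param mixing Optional explicit mixing matrix (e.g. `diag(n_sources)`)
#'   overriding the random draw.
#' @return List with `data` (`n_sources x n_samples`), `mixing`
#'   (`n_sources x n_sources`), `sources`.
#' @export
make_sparse_source_patches <- function(n_sources, n_samples,
                                       mixing_seed = 1, source_seed = 2,
                                       mixing = NULL) {
  stopifnot(n_samples > n_sources)
  s <- withr::with_seed(source_seed, {
    matrix(stats::rexp(n_sources * n_samples) *
             sample(c(-1, 1), n_sources * n_samples, replace = TRUE),
           n_sources, n_samples)
  })
  if (is.null(mixing)) {
    a <- withr::with_seed(mixing_seed, {
      m <- matrix(stats::rnorm(n_sources^2), n_sources, n_sources)
      tries <- 0
      while (rcond_sq(m) < 1e-6 && tries < 100) {
        m <- matrix(stats::rnorm(n_sources^2), n_sources, n_sources)
        tries <- tries + 1
      }
      m
    })
  } else {
    stopifnot(all(dim(mixing) == n_sources))
    a <- mixing
  }
  list(data = a %*% s, mixing = a, sources = s)
}

rcond_sq <- function(m) {
  sv <- svd(m, nu = 0, nv = 0)$d
  min(sv) / max(sv)
}
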