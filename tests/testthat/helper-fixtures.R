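# Shared fixtures: random admissible Gabor parameter draws, angle
# comparison helpers, and a compact one-cell analysis pipeline used by
# the heavier recovery tests.

# Random Gabor parameters inside the fitter's admissible box.
rand_gabor <- function() {
  gabor_params(theta = stats::runif(1, 0, pi),
               f = stats::runif(1, 0.08, 0.3),
               phi = stats::runif(1, 0, 2 * pi),
               sigma_w = stats::runif(1, 1.5, 4),
               sigma_h = stats::runif(1, 1.5, 4),
               psi = stats::runif(1, 0, pi),
               centre_x = stats::runif(1, -3, 3),
               centre_y = stats::runif(1, -3, 3),
               amplitude = stats::runif(1, 0.5, 2))
}

# Circular distance between carrier orientations (radians on [0, pi)).
theta_dist <- function(a, b) {
  d <- abs(a - b)
  min(d, pi - d)
}

# Circular distance between phases, after aligning carrier orientations
# the same way phase_disparity does.
phi_dist <- function(fit, true) {
  ph <- fit$phi
  if (abs(fit$theta - true$theta) > pi / 2) ph <- -ph
  abs(((ph - true$phi + pi) %% (2 * pi)) - pi)
}

# One analysis cell: patches -> normalize -> whiten -> ICA -> Gabor fits
# -> measure table. Returns the per-component data frame.
run_cell <- function(pair, region, n_patches, k, seed,
                     resolution = 4, width = 16, ratio_threshold = 0.25) {
  rp <- if (abs(pair$pitch - resolution) < 1e-9) pair
        else resample_pair(pair, resolution)
  ps <- sample_patches(rp, region, patch_geometry(width, resolution),
                       n_patches, rng_seed = seed)
  ps <- normalize_patchset(ps)
  wm <- fit_whitening(ps, k)
  ic <- suppressWarnings(
    fit_ica(whiten(wm, ps), rng_seed = seed + 1L, whitening = wm,
            patch_width = width))
  comps <- lapply(seq_len(k), function(i)
    fit_component(split_component(ic, i),
                  ratio_threshold = ratio_threshold))
  component_measures(comps, resolution)
}
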