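# binoica

Eccentricity-resolved Independent Component Analysis of binocular
natural images.

## The problem

Human binocular vision degrades away from the fovea, and the statistics
of binocular images themselves vary with visual-field position: scenes
with a ground plane put near (crossed) disparities below fixation and
far (uncrossed) disparities above it, and verged eyes induce vertical
disparities with a characteristic quadrant sign pattern. `binoica` asks
what an *unsupervised* first visual layer learns about all this. It cuts
binocular image patches from regions defined by eccentricity and
quadrant, learns sparse linear filters by ICA, fits a Gabor model to
each eye of each filter, and summarizes how the filters' binocularity
and disparity tunings change across the visual field.

## The model

Patches are per-eye centred and normalised, concatenated, renormalised

    x_e = (x._e - <x._e>) / |x._e - <x._e>|,   e in {l, r}
    x   = [x_l, x_r] / |[x_l, x_r]|

then PCA-whitened with truncation to the K highest-variance axes, and
unmixed by fixed-point ICA (log-cosh contrast, symmetric
decorrelation). Each unmixing row, mapped back through the whitening
transform, is a binocular *filter*; its left/right halves are fitted
independently with the 2-D Gabor

    g(x, y) = A exp(-x.^2 / 2 sigma_w^2 - y.^2 / 2 sigma_h^2) cos(2 pi f z + phi)

where `(x., y.)` are envelope-rotated (by `psi`), centre-shifted
coordinates and `z` is the carrier coordinate (orientation `theta`),
also measured from the envelope centre. Derived per-component measures:

- **binocular ratio** `min(E_l, E_r) / max(E_l, E_r)` on the raw filter
  energies (sum of squared weights);
- **position disparity** `dx, dy` — offset of the two envelope centres,
  arcmin (`dx > 0` = uncrossed/far, `dy > 0` = higher in the left eye);
- **phase disparity** `|phi_r - phi_l|` wrapped to `[0, pi]`
  (`pi` = anti-correlated), **orientation disparity** in `[0, 90]` deg;
- distribution summaries: unscaled MAD, mirror-asymmetry of the phase
  histogram about `pi/2`, Spearman rank correlation of `(dx, dy)`, and
  200-resample bootstrapped histograms with 95% percentile envelopes.

Because photographic calibrated stereo sets cannot ship with the
package, a synthetic verged-stereo generator stands in: a dead-leaves
texture (1/f-like spectrum plus the sparse edge structure ICA needs),
a depth map (uniform, matrix, or parametric ground plane) converted to
horizontal disparity via `d = I (1/D - 1/Z)`, a vertical-disparity
field `v = -gamma x y` with the verged-geometry quadrant signs, and
half-per-eye bilinear warping with ground truth returned.

## Worked example

Impose a uniform +8 arcmin (far) shift and recover it from the learned
components at 4 arcmin/sample:

```r
library(binoica)
geom  <- viewing_geometry(interocular_mm = 65, fixation_mm = 1000,
                          field_half_width = 320, pixel_pitch = 1)
scene <- scene_spec(uniform_disparity_depth(8, geom), vertical_gain = 0,
                    rng_seed = 1)
rendered <- render_stereo_pair(scene, geom)

pair4   <- resample_pair(rendered$pair, 4)
patches <- sample_patches(pair4, region_spec("all"), patch_geometry(16, 4),
                          n_patches = 10000, rng_seed = 2)
patches <- normalize_patchset(patches)
wm    <- fit_whitening(patches, k = 128)
model <- fit_ica(whiten(wm, patches), rng_seed = 3, whitening = wm,
                 patch_width = 16)
comps <- lapply(1:128, function(i) fit_component(split_component(model, i)))
tab   <- component_measures(comps, res = 4)
valid <- tab[tab$valid, ]
```

Output of this exact script:

```
whitening_model: 512 -> 128 axes, 96.7% variance retained
ica_model: 128 components, 109 iterations, converged
valid components: 20 / 128
median dx: 7.98 arcmin (imposed shift: +8)
median dy: 0.05 arcmin (imposed: 0)
MAD dx: 0.46, MAD dy: 0.17 arcmin
monocular proportion (ratio < 0.25): 0.133
```

The filters' left/right envelope offsets recover the imposed shift to a
twentieth of a sample; the vertical disparity is correctly near zero.
`run_analysis(analysis_config(...))` wraps this loop over all
region × resolution cells and adds the bootstrap summaries;
`report_json()` serializes the result deterministically.

A minimal CLI wraps the same stages:
`Rscript inst/cli/binoica.R simulate|sample|fit|report --config cfg.txt --seed 1 --out prefix`.

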