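# Eccentricity/quadrant region partition, bicubic resampling to a target
# sample resolution, and binocular patch extraction.

.BANDS <- list(centre = c(0, 150), mid = c(150, 300),
               outer = c(300, 600), all = c(0, 600))
.QUADRANTS <- c("all", "top-left", "top-right", "bottom-left", "bottom-right")

#' Region of the visual field
#'
#' One of the 12 analysis regions: an eccentricity band crossed with a
#' quadrant. Bands are half-open annuli in arcmin of eccentricity from
#' fixation: centre `[0, 150)`, mid `[150, 300)`, outer `[300, 600)`
#' (plus the convenience band `all` = `[0, 600)`). Quadrants are defined
#' by the signs of (azimuth, elevation); points exactly on a quadrant
#' boundary (azimuth 0 or elevation 0) belong to no quadrant and are
#' excluded from quadrant-partitioned sets.
#'
#' @param band `"centre"`, `"mid"`, `"outer"` or `"all"`.
#' @param quadrant `"all"`, `"top-left"`, `"top-right"`, `"bottom-left"`
#'   or `"bottom-right"`.
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(band = "all", quadrant = "all") {
  band <- match.arg(band, names(.BANDS))
  quadrant <- match.arg(quadrant, .QUADRANTS)
  structure(list(band = band, quadrant = quadrant,
                 band_lo = .BANDS[[band]][1], band_hi = .BANDS[[band]][2]),
            class = "region_spec")
}

#' @export
format.region_spec <- function(x, ...) paste0(x$band, "/", x$quadrant)

#' @export
print.region_spec <- function(x, ...) {
  cat(sprintf("region_spec: %s band [%g, %g) arcmin, quadrant %s\n",
              x$band, x$band_lo, x$band_hi, x$quadrant))
  invisible(x)
}

#' Region membership of a visual-field location
#'
#' Maps an (azimuth, elevation) location (arcmin from fixation) to its
#' eccentricity band and quadrant. Eccentricity is the radial distance
#' `sqrt(x^2 + y^2)`; bands are lower-inclusive half-open intervals;
#' locations at 600 arcmin or beyond belong to no band. Locations on a
#' quadrant boundary get quadrant `NA`.
#'
#' @param azimuth,elevation Arcmin from fixation (scalars).
#' @return A [region_spec()] with the location's band, or `NULL` beyond
#'   600 arcmin. The quadrant slot is the location's quadrant (`NA` on a
#'   boundary).
#' @export
region_of <- function(azimuth, elevation) {
  ecc <- sqrt(azimuth^2 + elevation^2)
  if (ecc >= 600) return(NULL)
  band <- if (ecc < 150) "centre" else if (ecc < 300) "mid" else "outer"
  quad <- if (azimuth == 0 || elevation == 0) NA_character_
  else if (azimuth < 0 && elevation > 0) "top-left"
  else if (azimuth > 0 && elevation > 0) "top-right"
  else if (azimuth < 0) "bottom-left"
  else "bottom-right"
  r <- region_spec(band, "all")
  r$quadrant <- quad
  r
}

# Vectorized membership test against a fixed region.
in_region <- function(region, azimuth, elevation) {
  ecc2 <- azimuth^2 + elevation^2
  ok <- ecc2 >= region$band_lo^2 & ecc2 < region$band_hi^2
  if (region$quadrant != "all") {
    q <- switch(region$quadrant,
      "top-left" = azimuth < 0 & elevation > 0,
      "top-right" = azimuth > 0 & elevation > 0,
      "bottom-left" = azimuth < 0 & elevation < 0,
      "bottom-right" = azimuth > 0 & elevation < 0)
    ok <- ok & q
  }
  ok
}

#' Patch geometry
#'
#' Square per-eye patches of `width x width` samples on a grid with
#' angular spacing `sample_resolution` arcmin/sample; the binocular
#' dimension is `2 * width^2`.
#'
#' @param width Patch side length in samples per eye.
#' @param sample_resolution Arcmin per sample, in `[1, 10]`.
#' @return An object of class `patch_geometry`.
#' @export
patch_geometry <- function(width = 16, sample_resolution = 4) {
  stopifnot(width >= 4, sample_resolution >= 1, sample_resolution <= 10)
  structure(list(width = width, sample_resolution = sample_resolution,
                 binocular_dim = 2L * width^2),
            class = "patch_geometry")
}

# ---- bicubic resampling --------------------------------------------------

# Keys cubic-convolution kernel, a = -0.5 (the classical bicubic kernel).
cubic_kernel <- function(t, a = -0.5) {
  t <- abs(t)
  ifelse(t < 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

# Dense n_out x n_in weight matrix for 1-D cubic resampling with
# anti-aliasing (kernel widened by 1/scale when downsampling). Out-of-range
# taps are folded onto the edge samples (edge replication).
resample_weights <- function(n_in, n_out) {
  scale <- n_out / n_in
  ksc <- min(scale, 1)
  support <- 2 / ksc
  w <- matrix(0, n_out, n_in)
  for (j in seq_len(n_out)) {
    u <- (j - 0.5) / scale + 0.5
    lo <- floor(u - support); hi <- ceiling(u + support)
    idx <- lo:hi
    wt <- cubic_kernel((u - idx) * ksc)
    keep <- wt != 0
    idx <- idx[keep]; wt <- wt[keep]
    idx <- pmin(pmax(idx, 1), n_in)
    for (k in seq_along(idx)) w[j, idx[k]] <- w[j, idx[k]] + wt[k]
    w[j, ] <- w[j, ] / sum(w[j, ])
  }
  w
}

#' Resample an image to a coarser sample resolution
#'
#' Separable bicubic (Keys cubic convolution, a = -0.5) downsampling with
#' anti-aliasing, mirroring the behaviour of standard `imresize`-style
#' bicubic rescaling. The angular extent of the image is preserved; only
#' the sampling density changes. Upsampling requests are refused.
#'
#' @param image Numeric matrix.
#' @param from_res Input resolution, arcmin/px.
#' @param to_res Output resolution, arcmin/sample; must be `>= from_res`.
#' @return Numeric matrix of size `round(n * from_res/to_res)` per side.
#' @export
resample_image <- function(image, from_res, to_res) {
  if (to_res < from_res)
    stop("upsampling requested (to_res < from_res); only downsampling is supported")
  if (to_res == from_res) return(image)
  nr_out <- round(nrow(image) * from_res / to_res)
  nc_out <- round(ncol(image) * from_res / to_res)
  wr <- resample_weights(nrow(image), nr_out)
  wc <- resample_weights(ncol(image), nc_out)
  wr %*% image %*% t(wc)
}

#' Resample a stereo pair to a target sample resolution
#'
#' Applies [resample_image()] to both eyes and recomputes the angular
#' coordinate vectors of the new sample grid (sample j of the output sits
#' at the angular position of input pixel `(j - 0.5) * to/from + 0.5`).
#'
#' @param pair A [stereo_pair()].
#' @param to_res Target resolution, arcmin/sample.
#' @return A [stereo_pair()] at `to_res`.
#' @export
resample_pair <- function(pair, to_res) {
  from_res <- pair$pitch
  left <- resample_image(pair$left, from_res, to_res)
  right <- resample_image(pair$right, from_res, to_res)
  u_row <- (seq_len(nrow(left)) - 0.5) * nrow(pair$left) / nrow(left) + 0.5
  u_col <- (seq_len(ncol(left)) - 0.5) * ncol(pair$left) / ncol(left) + 0.5
  stereo_pair(left, right, to_res,
              azimuth = stats::approx(seq_along(pair$azimuth), pair$azimuth,
                                      u_col, rule = 2)$y,
              elevation = stats::approx(seq_along(pair$elevation),
                                        pair$elevation, u_row, rule = 2)$y,
              margin = pair$margin)
}

# ---- patch extraction ----------------------------------------------------

#' Admissible patch positions for a region
#'
#' Enumerates the top-left grid corners of all `width x width` patches
#' that (a) lie fully inside the raster, (b) avoid the pair's contaminated
#' border margin, and (c) have their CENTRE inside the region (membership
#' is evaluated in original angular coordinates, so it is invariant to
#' sample resolution).
#'
#' @param pair A [stereo_pair()] already at the analysis resolution.
#' @param region A [region_spec()].
#' @param geometry A [patch_geometry()] matching the pair's pitch.
#' @return Data frame with columns `row`, `col` (top-left corner),
#'   `azimuth`, `elevation` (patch centre, arcmin).
#' @export
admissible_centres <- function(pair, region, geometry) {
  w <- geometry$width
  nr <- nrow(pair$left); nc <- ncol(pair$left)
  if (nr < w || nc < w) stop("patch does not fit inside the image")
  az_lim <- max(abs(pair$azimuth)) - pair$margin
  el_lim <- max(abs(pair$elevation)) - pair$margin
  rows <- seq_len(nr - w + 1)
  cols <- seq_len(nc - w + 1)
  az_c <- (pair$azimuth[cols] + pair$azimuth[cols + w - 1]) / 2
  el_c <- (pair$elevation[rows] + pair$elevation[rows + w - 1]) / 2
  ok_r <- abs(pair$elevation[rows]) <= el_lim &
    abs(pair$elevation[rows + w - 1]) <= el_lim
  ok_c <- abs(pair$azimuth[cols]) <= az_lim &
    abs(pair$azimuth[cols + w - 1]) <= az_lim
  grid <- expand.grid(row = rows[ok_r], col = cols[ok_c])
  az <- az_c[grid$col]
  el <- el_c[grid$row]
  keep <- in_region(region, az, el)
  data.frame(row = grid$row[keep], col = grid$col[keep],
             azimuth = az[keep], elevation = el[keep])
}

#' Cut a set of binocular patches from a stereo pair
#'
#' Draws `n_patches` positions uniformly at random (with replacement)
#' among the admissible grid positions of the region and cuts co-located
#' left and right patches — the same cyclopean coordinates in both eyes,
#' so any disparity is expressed in the data, not in the sampling. Rows of
#' the returned matrix are the raw (un-normalized) concatenations
#' `[left, right]`, each half in column-major patch order.
#'
#' @param pair A [stereo_pair()] at the analysis resolution.
#' @param region A [region_spec()].
#' @param geometry A [patch_geometry()]; its `sample_resolution` must
#'   match the pair's pitch.
#' @param n_patches Number of patches to draw (0 gives an empty set).
#' @param rng_seed Integer seed; positions are a pure function of it.
#' @return An object of class `patch_set`: list with `data`
#'   (`n_patches x binocular_dim` matrix), `geometry`, `region`,
#'   `positions`, `seed`.
#' @export
sample_patches <- function(pair, region, geometry, n_patches,
                           rng_seed = 1) {
  if (abs(pair$pitch - geometry$sample_resolution) > 1e-9)
    stop(sprintf("pair is at %g arcmin/sample but geometry expects %g; resample first",
                 pair$pitch, geometry$sample_resolution))
  adm <- admissible_centres(pair, region, geometry)
  if (nrow(adm) == 0 && n_patches > 0)
    stop(sprintf("region %s is empty at %g arcmin/sample after accounting for patch borders",
                 format(region), pair$pitch))
  w <- geometry$width
  if (n_patches == 0) {
    return(structure(list(data = matrix(0, 0, geometry$binocular_dim),
                          geometry = geometry, region = region,
                          positions = adm[0, ], seed = rng_seed),
                     class = "patch_set"))
  }
  pick <- withr::with_seed(rng_seed,
    sample.int(nrow(adm), n_patches, replace = TRUE))
  pos <- adm[pick, , drop = FALSE]
  nr <- nrow(pair$left)
  # linear indices of all patch pixels: column-major within the patch
  offs <- as.vector(outer(0:(w - 1), (0:(w - 1)) * nr, "+"))
  base <- (pos$col - 1) * nr + pos$row
  idx <- outer(base, offs, "+")
  x <- cbind(matrix(pair$left[idx], n_patches, w * w),
             matrix(pair$right[idx], n_patches, w * w))
  structure(list(data = x, geometry = geometry, region = region,
                 positions = pos, seed = rng_seed),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("patch_set: %d patches, %dx%d per eye @ %g arcmin/sample, region %s\n",
              nrow(x$data), x$geometry$width, x$geometry$width,
              x$geometry$sample_resolution, format(x$region)))
  invisible(x)
}

#' Write / read a patch set as tabular text with a JSON sidecar
#'
#' @param ps A [patch_set()][sample_patches()].
#' @param prefix Path prefix; writes `<prefix>.tsv` and `<prefix>.json`.
#' @return Invisibly, the sidecar path.
#' @export
write_patchset <- function(ps, prefix) {
  utils::write.table(ps$data, paste0(prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(width = ps$geometry$width,
               sample_resolution = ps$geometry$sample_resolution,
               band = ps$region$band, quadrant = ps$region$quadrant,
               seed = ps$seed, n_patches = nrow(ps$data),
               positions = ps$positions)
  side <- paste0(prefix, ".json")
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' @rdname write_patchset
#' @param prefix Path prefix used when writing.
#' @export
read_patchset <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  x <- as.matrix(utils::read.table(paste0(prefix, ".tsv"), sep = "\t"))
  dimnames(x) <- NULL
  structure(list(data = x,
                 geometry = patch_geometry(meta$width, meta$sample_resolution),
                 region = region_spec(meta$band,
                                      ifelse(is.na(meta$quadrant) ||
                                               is.null(meta$quadrant),
                                             "all", meta$quadrant)),
                 positions = as.data.frame(meta$positions),
                 seed = meta$seed),
            class = "patch_set")
}
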