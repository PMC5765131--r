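test_that("resampling preserves constants, identity, and the size rule", {
  img <- matrix(stats::rnorm(100 * 100), 100, 100)
  expect_identical(resample_image(img, 1, 1), img)
  cimg <- matrix(3.7, 80, 80)
  out <- resample_image(cimg, 1, 4)
  expect_equal(dim(out), c(20, 20))
  expect_equal(max(abs(out - 3.7)), 0, tolerance = 1e-12)
  # the study's raster: 1201 px at 1 arcmin/px -> ~300 samples at 4
  big <- matrix(0, 1201, 3)
  expect_equal(nrow(resample_image(big, 1, 4)), 300)
  expect_error(resample_image(img, 4, 2), "upsampling")
})

test_that("bicubic downsampling tracks a smooth surface", {
  x <- seq(0, 1, length.out = 200)
  img <- outer(sin(2 * pi * 2 * x), cos(2 * pi * 3 * x))
  out <- resample_image(img, 1, 4)
  u <- ((seq_len(50) - 0.5) * 4 + 0.5 - 1) / 199
  ref <- outer(sin(2 * pi * 2 * u), cos(2 * pi * 3 * u))
  expect_equal(out[5:46, 5:46], ref[5:46, 5:46], tolerance = 0.01)
})

test_that("region membership follows eccentricity bands and quadrants", {
  r0 <- region_of(0, 0)
  expect_equal(r0$band, "centre")
  expect_true(is.na(r0$quadrant))
  r1 <- region_of(-200, 210)  # eccentricity ~290
  expect_equal(r1$band, "mid")
  expect_equal(r1$quadrant, "top-left")
  expect_null(region_of(500, -500))  # radius 707 > 600
  # half-open bands, lower-inclusive
  expect_equal(region_of(150, 0)$band, "mid")
  expect_equal(region_of(299.999, 0)$band, "mid")
  expect_equal(region_of(300, 0)$band, "outer")
  expect_null(region_of(600, 0))
  # boundary points are excluded from every quadrant
  expect_true(is.na(region_of(0, 200)$quadrant))
  expect_true(is.na(region_of(200, 0)$quadrant))
  # vectorized membership agrees with the scalar definition
  withr::with_seed(8, {
    x <- stats::runif(300, -650, 650)
    y <- stats::runif(300, -650, 650)
    for (reg in list(region_spec("mid", "all"),
                     region_spec("outer", "bottom-right"),
                     region_spec("centre", "top-left"))) {
      got <- binoica:::in_region(reg, x, y)
      ref <- vapply(seq_along(x), function(i) {
        r <- region_of(x[i], y[i])
        !is.null(r) && r$band == reg$band &&
          (reg$quadrant == "all" ||
             (!is.na(r$quadrant) && r$quadrant == reg$quadrant))
      }, logical(1))
      expect_identical(got, ref)
    }
  })
})

test_that("admissible centres match a brute-force enumeration", {
  geom <- viewing_geometry(fixation_mm = 1000, field_half_width = 200)
  sc <- scene_spec(1000, vertical_gain = 0, rng_seed = 2)
  rnd <- render_stereo_pair(sc, geom)
  rp <- resample_pair(rnd$pair, 4)
  pg <- patch_geometry(16, 4)
  reg <- region_spec("centre")
  adm <- admissible_centres(rp, reg, pg)
  # oracle: exhaustive double loop over all top-left corners
  n <- nrow(rp$left); w <- 16
  lim_az <- max(abs(rp$azimuth)) - rp$margin
  lim_el <- max(abs(rp$elevation)) - rp$margin
  cnt <- 0L
  for (i in seq_len(n - w + 1)) for (j in seq_len(n - w + 1)) {
    az <- (rp$azimuth[j] + rp$azimuth[j + w - 1]) / 2
    el <- (rp$elevation[i] + rp$elevation[i + w - 1]) / 2
    in_bounds <- abs(rp$azimuth[j]) <= lim_az &&
      abs(rp$azimuth[j + w - 1]) <= lim_az &&
      abs(rp$elevation[i]) <= lim_el &&
      abs(rp$elevation[i + w - 1]) <= lim_el
    ecc <- sqrt(az^2 + el^2)
    if (in_bounds && ecc < 150) cnt <- cnt + 1L
  }
  expect_gt(cnt, 0)
  expect_equal(nrow(adm), cnt)
})

test_that("patch sampling is deterministic, region-faithful and co-located", {
  geom <- viewing_geometry(fixation_mm = 1000, field_half_width = 200)
  sc <- scene_spec(1000, vertical_gain = 0, rng_seed = 2)
  rnd <- render_stereo_pair(sc, geom)
  rp <- resample_pair(rnd$pair, 4)
  pg <- patch_geometry(16, 4)
  reg <- region_spec("centre")

  ps0 <- sample_patches(rp, reg, pg, 0)
  expect_equal(nrow(ps0$data), 0)
  expect_equal(ncol(ps0$data), 512)

  ps1 <- sample_patches(rp, reg, pg, 500, rng_seed = 42)
  ps2 <- sample_patches(rp, reg, pg, 500, rng_seed = 42)
  expect_identical(ps1$data, ps2$data)
  expect_identical(ps1$positions, ps2$positions)
  # every emitted centre is inside the region
  expect_true(all(binoica:::in_region(reg, ps1$positions$azimuth,
                                      ps1$positions$elevation)))
  # zero-disparity scene: left and right patches are identical
  expect_equal(ps1$data[, 1:256], ps1$data[, 257:512])
  # empty region errors
  expect_error(sample_patches(rp, region_spec("outer"), pg, 10), "empty")
})

test_that("patch sets round-trip through their text serialization", {
  geom <- viewing_geometry(fixation_mm = 1000, field_half_width = 120)
  rnd <- render_stereo_pair(scene_spec(1000, rng_seed = 4), geom)
  rp <- resample_pair(rnd$pair, 4)
  ps <- sample_patches(rp, region_spec("centre", "top-right"),
                       patch_geometry(8, 4), 40, rng_seed = 5)
  pre <- file.path(withr::local_tempdir(), "ps")
  write_patchset(ps, pre)
  back <- read_patchset(pre)
  expect_equal(back$data, ps$data, tolerance = 1e-12)
  expect_equal(back$region$band, "centre")
  expect_equal(back$region$quadrant, "top-right")
})

test_that("stereo pairs round-trip through PGM text files", {
  geom <- viewing_geometry(fixation_mm = 1000, field_half_width = 60)
  rnd <- render_stereo_pair(scene_spec(900, rng_seed = 6), geom)
  pre <- file.path(withr::local_tempdir(), "pair")
  write_stereo_pair(rnd$pair, pre)
  back <- read_stereo_pair(pre)
  # 16-bit quantization: relative error bounded by the code step
  step <- diff(range(rnd$pair$left)) / 65535
  expect_lt(max(abs(back$left - rnd$pair$left)), step)
  expect_equal(back$azimuth, rnd$pair$azimuth)
  expect_equal(back$elevation, rnd$pair$elevation)
})
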