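test_that("flat depth at fixation with zero vertical gain gives identical eyes", {
  geom <- viewing_geometry(fixation_mm = 1000, field_half_width = 60)
  sc <- scene_spec(depth = 1000, vertical_gain = 0, rng_seed = 3)
  rnd <- render_stereo_pair(sc, geom)
  expect_identical(rnd$pair$left, rnd$pair$right)
  expect_true(all(rnd$truth$horizontal == 0))
  expect_true(all(rnd$truth$vertical == 0))
})

test_that("uniform imposed shift is recovered by a cross-correlation oracle", {
  geom <- viewing_geometry(fixation_mm = 1000, field_half_width = 100)
  d0 <- 8
  sc <- scene_spec(uniform_disparity_depth(d0, geom), vertical_gain = 0,
                   rng_seed = 7)
  rnd <- render_stereo_pair(sc, geom)
  expect_equal(max(abs(rnd$truth$horizontal - d0)), 0, tolerance = 1e-9)
  # brute-force oracle: correlate interior rows of the two eyes at
  # integer lags; L(x) = T(x + d0/2), R(x) = T(x - d0/2) => L(x) = R(x + d0)
  lags <- -12:12
  for (row in c(60, 101, 140)) {
    cols <- 41:161
    sc_lag <- vapply(lags, function(k) {
      stats::cor(rnd$pair$left[row, cols], rnd$pair$right[row, cols + k])
    }, numeric(1))
    expect_equal(lags[which.max(sc_lag)], d0)
  }
})

test_that("ground-plane scenes are near below fixation and far above", {
  geom <- viewing_geometry(fixation_mm = 1800, field_half_width = 600)
  sc <- scene_spec(ground_plane(eye_height_mm = 1600), rng_seed = 5)
  rnd <- render_stereo_pair(sc, geom)
  el <- rnd$pair$elevation
  dx <- rnd$truth$horizontal
  expect_true(median(dx[el < 0, ]) < 0)  # below fixation: crossed/near
  expect_true(median(dx[el > 0, ]) > 0)  # above fixation: uncrossed/far
  # monotone non-decreasing with elevation (column profile)
  prof <- dx[, 601]
  expect_true(all(diff(rev(prof)) >= -1e-9))
})

test_that("warp round-trip recovers a band-limited texture within 2% RMS", {
  geom <- viewing_geometry(fixation_mm = 1000, field_half_width = 100)
  sc <- scene_spec(uniform_disparity_depth(6, geom), vertical_gain = 1e-4,
                   texture_model = "gaussian", texture_cutoff = 0.15,
                   rng_seed = 11)
  rnd <- render_stereo_pair(sc, geom)
  n <- nrow(rnd$texture)
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  # left sampled T at (x + d/2, y - v/2): invert by sampling left at
  # (x - d/2, y + v/2)
  d <- rnd$truth$horizontal; v <- rnd$truth$vertical
  back <- binoica:::bilinear_sample(rnd$pair$left, rows - (v / 2),
                                    cols - (d / 2))
  interior <- 20:(n - 20)
  err <- back[interior, interior] - rnd$texture[interior, interior]
  rms <- sqrt(mean(err^2)) / stats::sd(rnd$texture[interior, interior])
  expect_lt(rms, 0.02)
})

test_that("disparities beyond the warp budget are refused", {
  geom <- viewing_geometry(fixation_mm = 1000, field_half_width = 60)
  sc <- scene_spec(uniform_disparity_depth(50, geom), rng_seed = 1)
  expect_error(render_stereo_pair(sc, geom, warp_budget = 10), "warp budget")
})

test_that("the generator is a pure function of its seeds", {
  geom <- viewing_geometry(fixation_mm = 1000, field_half_width = 80)
  sc <- scene_spec(1200, vertical_gain = 2e-5, rng_seed = 9)
  r1 <- render_stereo_pair(sc, geom)
  r2 <- render_stereo_pair(sc, geom)
  expect_identical(r1$pair$left, r2$pair$left)
  expect_identical(r1$pair$right, r2$pair$right)
  r3 <- render_stereo_pair(scene_spec(1200, vertical_gain = 2e-5,
                                      rng_seed = 10), geom)
  expect_false(identical(r1$pair$left, r3$pair$left))
})

test_that("textures have the stated statistics", {
  tx <- synth_texture(128, seed = 2)
  expect_equal(mean(tx), 0, tolerance = 1e-12)
  expect_equal(stats::sd(tx), 1, tolerance = 1e-12)
  # dead leaves must be non-Gaussian (positive excess kurtosis of
  # derivatives, the sparse-edge signature)
  dtx <- diff(tx)
  kurt <- mean(dtx^4) / mean(dtx^2)^2 - 3
  expect_gt(kurt, 0.5)
  # gaussian spectral model: radially averaged amplitude falls ~ 1/f
  tg <- synth_texture(256, alpha = 1, seed = 3, model = "gaussian")
  a <- Mod(stats::fft(tg))
  f1 <- ifelse(0:255 <= 128, 0:255, 0:255 - 256) / 256
  fr <- sqrt(outer(f1^2, f1^2, "+"))
  band <- function(lo, hi) mean(a[fr >= lo & fr < hi])
  ratio <- band(0.02, 0.04) / band(0.16, 0.32)
  expect_gt(ratio, 4)  # ~8 expected for 1/f with octave-spaced bands
})

test_that("gabor patch fixture matches an independent evaluation of the model", {
  p <- gabor_params(theta = 0.6, f = 0.15, phi = 1.2, sigma_w = 2.5,
                    sigma_h = 3, psi = 0.3, centre_x = 1, centre_y = -1,
                    amplitude = 1.4)
  patch <- make_gabor_patch(p, 17)
  # independent re-evaluation of the Gabor model, written separately
  xs <- -8:8
  ref <- matrix(0, 17, 17)
  for (i in 1:17) for (j in 1:17) {
    x <- xs[j] - p$centre_x
    y <- rev(xs)[i] - p$centre_y
    xr <- x * cos(p$psi) - y * sin(p$psi)
    yr <- x * sin(p$psi) + y * cos(p$psi)
    z <- x * cos(p$theta) - y * sin(p$theta)
    ref[i, j] <- p$amplitude *
      exp(-xr^2 / (2 * p$sigma_w^2) - yr^2 / (2 * p$sigma_h^2)) *
      cos(2 * pi * p$f * z + p$phi)
  }
  expect_equal(patch, ref, tolerance = 1e-12)
  # centre-pixel values (odd patch => x = y = 0 exists)
  pc <- gabor_params(theta = 0.3, f = 0.2, phi = 0, sigma_w = 2,
                     sigma_h = 2, amplitude = 1.7)
  expect_equal(make_gabor_patch(pc, 17)[9, 9], 1.7)
  pq <- gabor_params(theta = 0.3, f = 0.2, phi = pi / 2, sigma_w = 2,
                     sigma_h = 2)
  expect_equal(make_gabor_patch(pq, 17)[9, 9], 0, tolerance = 1e-12)
  expect_error(make_gabor_patch(pc, 3))
  p_bad <- p; p_bad$f <- 0.6
  expect_error(make_gabor_patch(p_bad, 17), "Nyquist")
})

test_that("sparse source fixture: identity mixing, rank, determinism", {
  m1 <- make_sparse_source_patches(6, 500, mixing = diag(6))
  expect_identical(m1$data, m1$sources)
  m2 <- make_sparse_source_patches(8, 1000, mixing_seed = 3, source_seed = 4)
  expect_equal(qr(m2$mixing)$rank, 8)
  m3 <- make_sparse_source_patches(8, 1000, mixing_seed = 3, source_seed = 4)
  expect_identical(m2, m3)
  # heavy-tailed: excess kurtosis of a double exponential is 3
  expect_gt(mean(m2$sources^4) / mean(m2$sources^2)^2 - 3, 1.5)
})
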