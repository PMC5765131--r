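test_that("bootstrap histograms behave on degenerate inputs", {
  bh <- bootstrap_histogram(rep(2, 50), bin_edges = 0:5, n_boot = 50,
                            seed = 1)
  expect_equal(bh$median_curve, c(0, 0, 1, 0, 0))
  expect_equal(bh$ci_low, bh$ci_high)
  expect_error(bootstrap_histogram(numeric(0), 0:5), "no values")
})

test_that("bootstrap histograms match an independent resampling oracle", {
  withr::with_seed(2, values <- stats::rnorm(300))
  edges <- seq(-3, 3, length.out = 13)
  bh <- bootstrap_histogram(values, edges, n_boot = 100, seed = 77)
  # oracle: re-implement the resampling with the same seed stream
  oracle <- withr::with_seed(77, {
    t(vapply(1:100, function(b) {
      v <- sample(values, length(values), replace = TRUE)
      v <- v[v >= edges[1] & v <= edges[13]]
      h <- tabulate(pmin(findInterval(v, edges), 12), nbins = 12)
      h / sum(h)
    }, numeric(12)))
  })
  expect_equal(bh$median_curve, apply(oracle, 2, stats::median))
  expect_equal(bh$ci_low,
               apply(oracle, 2, stats::quantile, 0.025, names = FALSE))
  expect_true(all(bh$ci_low <= bh$median_curve + 1e-12) &&
                all(bh$median_curve <= bh$ci_high + 1e-12))
  # n_boot = 1: the median curve IS that single resample's histogram
  b1 <- bootstrap_histogram(values, edges, n_boot = 1, seed = 5)
  o1 <- withr::with_seed(5, {
    v <- sample(values, length(values), replace = TRUE)
    h <- tabulate(pmin(findInterval(v, edges), 12), nbins = 12)
    h / sum(h)
  })
  expect_equal(b1$median_curve, o1)
})

test_that("spearman correlation matches the rank formula", {
  s <- spearman_dx_dy(1:10, (1:10)^3)
  expect_equal(s$rho, 1)
  # hand evaluation of 1 - 6*sum(d^2)/(n(n^2-1))
  s2 <- spearman_dx_dy(c(1, 2, 3), c(3, 1, 2))
  expect_equal(s2$rho, -0.5)
  expect_error(spearman_dx_dy(1:4, 1:5), "equal length")
  expect_error(spearman_dx_dy(1:2, 2:1), "at least 3")
})

test_that("spearman p-values hold their nominal type-I error rate", {
  withr::with_seed(99, {
    hits <- vapply(1:100, function(i) {
      spearman_dx_dy(stats::rnorm(500), stats::rnorm(500))$p > 0.05
    }, logical(1))
  })
  # ~95% expected; binomial(100, .95) 3 sd band
  expect_gte(mean(hits), 0.88)
})

test_that("the analysis runner records per-cell errors and carries on", {
  geom <- viewing_geometry(fixation_mm = 1000, field_half_width = 150)
  sc <- scene_spec(1050, vertical_gain = 0, rng_seed = 3)
  # outer band is unreachable at a 150-arcmin half-field -> cell error
  cfg <- analysis_config(scene = sc, geometry = geom,
                         regions = list(region_spec("centre"),
                                        region_spec("outer")),
                         resolutions = 4, patch_width = 8,
                         n_patches = 800, k = 12, n_boot = 20, seed = 2,
                         ica_max_iter = 200)
  rep <- suppressWarnings(run_analysis(cfg))
  expect_named(rep$cells, c("centre/all@4", "outer/all@4"))
  expect_match(rep$cells[["outer/all@4"]]$error, "empty")
  s <- rep$cells[["centre/all@4"]]$summary
  expect_equal(s$n_components, 12)
  expect_true(s$monocular_proportion >= 0 && s$monocular_proportion <= 1)
  expect_true(s$valid_proportion >= 0 && s$valid_proportion <= 1)
  # monocular + binocular proportions partition the components
  expect_equal(s$monocular_proportion +
                 mean(rep$cells[["centre/all@4"]]$measures$binocular_ratio >=
                        0.25), 1)
  # report serializes and echoes its configuration
  js <- report_json(rep)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$config$seed, 2)
  expect_equal(parsed$config$k, 12)
})

test_that("measure tables export as tidy text", {
  geom <- viewing_geometry(fixation_mm = 1000, field_half_width = 120)
  sc <- scene_spec(1050, vertical_gain = 0, rng_seed = 4)
  cfg <- analysis_config(scene = sc, geometry = geom,
                         regions = list(region_spec("centre")),
                         resolutions = 4, patch_width = 8,
                         n_patches = 800, k = 10, n_boot = 10, seed = 3,
                         ica_max_iter = 200)
  rep <- suppressWarnings(run_analysis(cfg))
  path <- file.path(withr::local_tempdir(), "measures.tsv")
  tab <- write_measure_table(rep, path)
  back <- utils::read.delim(path)
  expect_equal(nrow(back), 10)
  expect_true(all(c("region", "resolution", "dx", "dy", "dphi",
                    "binocular_ratio") %in% names(back)))
})

test_that("the CLI wires simulate through to files", {
  dir <- withr::local_tempdir()
  cfgf <- file.path(dir, "cfg.txt")
  writeLines(c("geometry.field_half_width = 80",
               "scene.depth_mm = 1000",
               "scene.vertical_gain = 0"), cfgf)
  out <- file.path(dir, "sim")
  expect_message(
    binoica_cli(c("simulate", "--config", cfgf, "--seed", "4",
                  "--out", out)), "wrote")
  expect_true(file.exists(paste0(out, "_L.pgm")))
  expect_true(file.exists(paste0(out, "_truth_dx.tsv")))
  pair <- read_stereo_pair(out)
  expect_equal(dim(pair$left), c(161, 161))
})
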