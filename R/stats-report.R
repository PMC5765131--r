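# Bootstrapped distribution summaries and the end-to-end analysis
# pipeline over (region x resolution) cells.

#' Bootstrapped histogram with percentile confidence envelope
#'
#' Resamples the value set (the per-component measurements — the
#' resampling unit is the component) with replacement `n_boot` times,
#' histograms each resample on fixed bin edges, normalizes each histogram
#' to sum 1, and reports the per-bin median and 2.5/97.5 percentile
#' envelope.
#'
#' @param values Numeric vector, length `>= 1` (length `>= 2` for a
#'   meaningful envelope). Values outside the edges are dropped.
#' @param bin_edges Increasing vector of bin edges.
#' @param n_boot Number of bootstrap resamples; default 200.
#' @param seed Integer seed.
#' @return An object of class `bootstrap_histogram`: `bin_edges`,
#'   `median_curve`, `ci_low`, `ci_high`, `n_boot`, `seed`.
#' @export
bootstrap_histogram <- function(values, bin_edges, n_boot = 200, seed = 1) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("no values to bootstrap")
  nb <- length(bin_edges) - 1
  count_hist <- function(v) {
    v <- v[v >= bin_edges[1] & v <= bin_edges[nb + 1]]
    idx <- pmin(findInterval(v, bin_edges), nb)
    h <- tabulate(idx, nbins = nb)
    if (sum(h) > 0) h / sum(h) else h
  }
  mat <- withr::with_seed(seed, {
    t(vapply(seq_len(n_boot), function(b) {
      count_hist(sample(values, length(values), replace = TRUE))
    }, numeric(nb)))
  })
  qs <- apply(mat, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
              names = FALSE)
  structure(list(bin_edges = bin_edges, median_curve = qs[2, ],
                 ci_low = qs[1, ], ci_high = qs[3, ],
                 n_boot = n_boot, seed = seed),
            class = "bootstrap_histogram")
}

#' Spearman rank correlation between horizontal and vertical disparities
#'
#' Tie-corrected rank correlation with a two-sided p-value (delegated to
#' [stats::cor.test()] with the large-sample approximation, which is
#' exact in the tie-corrected-rank sense).
#'
#' @param dx,dy Equal-length numeric vectors, length `>= 3`.
#' @return List with `rho` and `p`.
#' @export
spearman_dx_dy <- function(dx, dy) {
  if (length(dx) != length(dy)) stop("dx and dy must have equal length")
  if (length(dx) < 3) stop("need at least 3 pairs")
  ct <- suppressWarnings(
    stats::cor.test(dx, dy, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Configuration for a full analysis run
#'
#' @param scene A [scene_spec()] (the synthetic stand-in for the image
#'   set) or a pre-rendered result of [render_stereo_pair()].
#' @param geometry A [viewing_geometry()].
#' @param regions List of [region_spec()]; default the three radial
#'   eccentricity bands.
#' @param resolutions Sample resolutions to analyse, arcmin/sample.
#' @param patch_width Per-eye patch side, samples; default 16.
#' @param n_patches Patches per cell; default 50000.
#' @param k Retained PCA/ICA components; default 250.
#' @param ratio_threshold Binocular-ratio validity threshold;
#'   default 0.25 (use 0.5 for the quadrant-style analysis).
#' @param accept A [gabor_accept_config()].
#' @param n_boot Bootstrap resamples; default 200.
#' @param seed Integer seed block base; every random stage of every cell
#'   derives its own sub-seed from it.
#' @param ica_tol,ica_max_iter Fixed-point ICA stopping parameters.
#' @param bins Histogram bin counts: `disparity` (21), `phase` (32),
#'   `orientation` (18), `frequency` (20).
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(scene, geometry,
                            regions = list(region_spec("centre"),
                                           region_spec("mid"),
                                           region_spec("outer")),
                            resolutions = 4, patch_width = 16,
                            n_patches = 50000, k = 250,
                            ratio_threshold = 0.25,
                            accept = gabor_accept_config(),
                            n_boot = 200, seed = 1,
                            ica_tol = 1e-4, ica_max_iter = 1000,
                            bins = c(disparity = 21, phase = 32,
                                     orientation = 18, frequency = 20)) {
  structure(list(scene = scene, geometry = geometry, regions = regions,
                 resolutions = resolutions, patch_width = patch_width,
                 n_patches = n_patches, k = k,
                 ratio_threshold = ratio_threshold, accept = accept,
                 n_boot = n_boot, seed = as.integer(seed),
                 ica_tol = ica_tol, ica_max_iter = ica_max_iter,
                 bins = bins),
            class = "analysis_config")
}

# Deterministic sub-seed derivation (kept below 2^31).
cell_seed <- function(base, cell, stage) {
  (base * 1009L + cell * 101L + stage) %% .Machine$integer.max
}

#' Analyse one (region x resolution) cell
#'
#' The full pipeline for one cell: resample, cut patches, normalize,
#' whiten, ICA, split components, fit Gabors, derive the disparity
#' measures and their bootstrap summaries.
#'
#' @param pair A full-resolution [stereo_pair()].
#' @param region A [region_spec()].
#' @param resolution Arcmin/sample.
#' @param config An [analysis_config()].
#' @param cell Integer cell index (drives the sub-seeds).
#' @return List with the measure table, summaries, and the fitted models.
#' @export
analyse_cell <- function(pair, region, resolution, config, cell = 1L) {
  res_pair <- if (abs(pair$pitch - resolution) < 1e-9) pair
              else resample_pair(pair, resolution)
  geom <- patch_geometry(config$patch_width, resolution)
  ps <- sample_patches(res_pair, region, geom, config$n_patches,
                       rng_seed = cell_seed(config$seed, cell, 1L))
  ps <- normalize_patchset(ps)
  wm <- fit_whitening(ps, k = config$k)
  y <- whiten(wm, ps)
  ica <- fit_ica(y, rng_seed = cell_seed(config$seed, cell, 2L),
                 tol = config$ica_tol, max_iter = config$ica_max_iter,
                 whitening = wm, patch_width = config$patch_width)
  comps <- lapply(seq_len(config$k), function(i) {
    fit_component(split_component(ica, i), accept = config$accept,
                  ratio_threshold = config$ratio_threshold)
  })
  tab <- component_measures(comps, resolution)

  bseed <- cell_seed(config$seed, cell, 3L)
  nb <- config$bins
  hw <- config$patch_width * resolution / 2
  valid <- tab[tab$valid, , drop = FALSE]
  summ <- list(
    n_components = nrow(tab),
    monocular_proportion = mean(tab$binocular_ratio < config$ratio_threshold),
    valid_proportion = mean(tab$valid),
    variance_fraction = wm$variance_fraction,
    converged = ica$converged)
  if (nrow(valid) >= 2) {
    summ$freq_hist <- bootstrap_histogram(
      valid$freq, seq(0, 0.5, length.out = nb[["frequency"]] + 1),
      config$n_boot, bseed)
    summ$dx_hist <- bootstrap_histogram(
      valid$dx, seq(-hw, hw, length.out = nb[["disparity"]] + 1),
      config$n_boot, bseed + 1L)
    summ$dy_hist <- bootstrap_histogram(
      valid$dy, seq(-hw, hw, length.out = nb[["disparity"]] + 1),
      config$n_boot, bseed + 2L)
    summ$phase_hist <- bootstrap_histogram(
      valid$dphi, seq(0, pi, length.out = nb[["phase"]] + 1),
      config$n_boot, bseed + 3L)
    summ$orientation_hist <- bootstrap_histogram(
      valid$dtheta, seq(0, 90, length.out = nb[["orientation"]] + 1),
      config$n_boot, bseed + 4L)
    summ$dx_mad <- mad_stat(valid$dx)
    summ$dy_mad <- mad_stat(valid$dy)
    summ$dx_median <- stats::median(valid$dx)
    summ$dy_median <- stats::median(valid$dy)
    summ$orientation_mad <- mad_stat(valid$dtheta)
    summ$phase_asymmetry <- asymmetry(summ$phase_hist$median_curve /
                                        sum(summ$phase_hist$median_curve))
    if (nrow(valid) >= 3)
      summ$spearman <- spearman_dx_dy(valid$dx, valid$dy)
  }
  list(region = format(region), resolution = resolution,
       measures = tab, summary = summ, ica = ica, whitening = wm)
}

#' Run the full eccentricity/quadrant analysis
#'
#' Renders (or accepts) a stereo pair and runs [analyse_cell()] for every
#' region x resolution combination. Each cell gets its own deterministic
#' seed block derived from `config$seed`; an error in one cell is
#' recorded and the run continues. The report (without the fitted models)
#' is serializable with [report_json()]; two runs with the same
#' configuration produce byte-identical reports.
#'
#' @param config An [analysis_config()].
#' @param keep_models Keep the per-cell ICA/whitening models in the
#'   return value (default FALSE; the report itself never contains them).
#' @return An object of class `analysis_report`.
#' @export
run_analysis <- function(config, keep_models = FALSE) {
  rendered <- if (inherits(config$scene, "scene_spec"))
    render_stereo_pair(config$scene, config$geometry)
  else config$scene
  pair <- rendered$pair

  cells <- list()
  models <- list()
  cell_id <- 0L
  for (res in config$resolutions) {
    for (region in config$regions) {
      cell_id <- cell_id + 1L
      key <- sprintf("%s@%g", format(region), res)
      out <- tryCatch(
        analyse_cell(pair, region, res, config, cell_id),
        error = function(e) list(region = format(region),
                                 resolution = res,
                                 error = conditionMessage(e)))
      if (keep_models && !is.null(out$ica))
        models[[key]] <- list(ica = out$ica, whitening = out$whitening)
      out$ica <- NULL; out$whitening <- NULL
      cells[[key]] <- out
    }
  }
  structure(list(
    config_echo = list(
      seed = config$seed, n_patches = config$n_patches, k = config$k,
      patch_width = config$patch_width,
      resolutions = config$resolutions,
      regions = vapply(config$regions, format, character(1)),
      ratio_threshold = config$ratio_threshold, n_boot = config$n_boot),
    cells = cells,
    models = if (keep_models) models else NULL),
    class = "analysis_report")
}

#' Serialize an analysis report to canonical JSON
#'
#' Deterministic given the report: identical runs serialize to identical
#' strings.
#'
#' @param report An [run_analysis()] report.
#' @param path Optional file path to write to.
#' @return The JSON string, invisibly when `path` is given.
#' @export
report_json <- function(report, path = NULL) {
  strip <- function(v) {
    if (is.list(v)) lapply(unclass(v), strip) else v
  }
  x <- list(config = report$config_echo,
            cells = lapply(report$cells, function(cl) {
              cl$measures <- NULL  # tidy table exported separately
              strip(cl)
            }))
  js <- jsonlite::toJSON(x, digits = NA, auto_unbox = TRUE, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    invisible(js)
  } else js
}

#' Write the per-component measure tables of a report as tidy TSV
#'
#' One row per component, keyed by region and resolution.
#'
#' @param report An [run_analysis()] report.
#' @param path Output TSV path.
#' @return Invisibly, the combined data frame.
#' @export
write_measure_table <- function(report, path) {
  tabs <- lapply(names(report$cells), function(key) {
    cl <- report$cells[[key]]
    if (is.null(cl$measures)) return(NULL)
    cbind(region = cl$region, resolution = cl$resolution, cl$measures)
  })
  tab <- do.call(rbind, tabs)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(tab)
}
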