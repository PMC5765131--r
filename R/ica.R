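# Fixed-point ICA on whitened binocular patches and per-component
# binocular structure.

#' Fit independent components by fixed-point iteration
#'
#' Symmetric FastICA with the log-cosh contrast (`g = tanh`): starting
#' from a seeded random orthogonal unmixing matrix, iterate the
#' fixed-point update and re-orthonormalize by symmetric decorrelation
#' until the largest change in any component direction falls below `tol`.
#' The unmixing rows are unit-norm (orthonormal) in whitened space.
#'
#' Components are canonicalized for reproducibility: ordered by
#' descending response kurtosis, and signed so that the response skewness
#' is non-negative (when the skewness is numerically zero, the largest
#' absolute filter weight is made positive instead).
#'
#' @param x Whitened data, `n x k` matrix (identity covariance).
#' @param rng_seed Integer seed for the initial matrix.
#' @param tol Convergence tolerance on `max |1 - |<w_new, w_old>||`;
#'   default 1e-4.
#' @param max_iter Maximum fixed-point iterations; default 1000. If the
#'   tolerance is not reached a warning is raised and the model flagged.
#' @param whitening Optional [fit_whitening()] model; when supplied, the
#'   pixel-space filters `unmixing %*% t(axes/sdev)` are attached so
#'   components can be split and analysed.
#' @param patch_width Optional per-eye patch width, attached for
#'   [split_component()].
#' @return An object of class `ica_model`: `unmixing` (`k x k`, rows =
#'   filters in whitened space), `filters` (`k x d` pixel-space filters,
#'   if `whitening` given), `kurtosis`, `iterations`, `converged`,
#'   `identifiable`, `seed`, `tol`.
#' @export
fit_ica <- function(x, rng_seed = 1, tol = 1e-4, max_iter = 1000,
                    whitening = NULL, patch_width = NULL) {
  k <- ncol(x)
  n <- nrow(x)
  if (n <= 10 * k)
    warning(sprintf("only %d samples for %d components; estimates may be unstable", n, k))
  xt <- t(x)  # k x n

  sym_decorr <- function(w) {
    e <- eigen(w %*% t(w), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300)), k) %*%
      t(e$vectors) %*% w
  }

  w <- withr::with_seed(rng_seed, matrix(stats::rnorm(k * k), k, k))
  w <- sym_decorr(w)
  iter <- 0L
  conv <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    u <- w %*% xt
    g <- tanh(u)
    w1 <- g %*% x / n - diag(rowMeans(1 - g^2), k) %*% w
    w1 <- sym_decorr(w1)
    conv <- max(abs(abs(rowSums(w1 * w)) - 1))
    w <- w1
    if (conv < tol) break
  }
  converged <- conv < tol
  if (!converged)
    warning(sprintf("ICA did not converge in %d iterations (delta %.2e); model flagged",
                    max_iter, conv))

  u <- w %*% xt
  m2 <- rowMeans(u^2)
  kurt <- rowMeans(u^4) / m2^2 - 3
  skew <- rowMeans(u^3) / m2^1.5
  identifiable <- any(abs(kurt) > 0.1)
  if (!identifiable)
    warning("responses are near-Gaussian on every component; ICA is not identifiable")

  ord <- order(kurt, decreasing = TRUE)
  w <- w[ord, , drop = FALSE]
  kurt <- kurt[ord]; skew <- skew[ord]
  sgn <- ifelse(abs(skew) > 1e-8, sign(skew), 0)
  model <- structure(list(unmixing = w, kurtosis = kurt,
                          iterations = iter, converged = converged,
                          identifiable = identifiable,
                          seed = rng_seed, tol = tol,
                          whitening = whitening,
                          patch_width = patch_width),
                     class = "ica_model")
  if (!is.null(whitening)) {
    filt <- unwhiten_filter(whitening, w)
    # sign canonicalization on the analysis objects (the filters)
    for (i in seq_len(k)) {
      s <- if (sgn[i] != 0) sgn[i] else sign(filt[i, which.max(abs(filt[i, ]))])
      filt[i, ] <- s * filt[i, ]
      model$unmixing[i, ] <- s * model$unmixing[i, ]
    }
    model$filters <- filt
  } else {
    for (i in seq_len(k)) {
      s <- if (sgn[i] != 0) sgn[i] else
        sign(model$unmixing[i, which.max(abs(model$unmixing[i, ]))])
      model$unmixing[i, ] <- s * model$unmixing[i, ]
    }
  }
  model
}

#' @export
print.ica_model <- function(x, ...) {
  cat(sprintf("ica_model: %d components, %d iterations, %sconverged\n",
              nrow(x$unmixing), x$iterations,
              if (x$converged) "" else "NOT "))
  invisible(x)
}

#' Split a pixel-space filter into its binocular structure
#'
#' Reshapes one component's pixel-space filter into its left- and
#' right-eye halves and computes the per-eye energies (sum of squared
#' filter weights) and the binocular energy ratio
#' `min(E_l, E_r) / max(E_l, E_r)`. The ratio is a property of the raw
#' filter weights and is unaffected by any later Gabor fitting.
#'
#' @param model An [fit_ica()] model fitted with `whitening` and
#'   `patch_width` attached, or a plain numeric filter vector.
#' @param index Component index (when `model` is an `ica_model`).
#' @param width Per-eye patch width (required for a plain vector).
#' @return An object of class `binocular_component`: `left_weights`,
#'   `right_weights` (`width x width` matrices, row 1 = top),
#'   `left_energy`, `right_energy`, `binocular_ratio`, `gabor_left`,
#'   `gabor_right` (NULL until fitted), `valid` (NA until fitted),
#'   `index`.
#' @export
split_component <- function(model, index = NULL, width = NULL) {
  if (inherits(model, "ica_model")) {
    if (is.null(model$filters))
      stop("model has no pixel-space filters; refit with `whitening =`")
    stopifnot(index >= 1, index <= nrow(model$filters))
    f <- model$filters[index, ]
    width <- model$patch_width
  } else {
    f <- model
  }
  if (is.null(width)) stop("patch width is required")
  d <- width^2
  stopifnot(length(f) == 2 * d)
  lw <- matrix(f[seq_len(d)], width, width)
  rw <- matrix(f[d + seq_len(d)], width, width)
  el <- sum(lw^2); er <- sum(rw^2)
  ratio <- if (max(el, er) == 0) 0 else min(el, er) / max(el, er)
  structure(list(left_weights = lw, right_weights = rw,
                 left_energy = el, right_energy = er,
                 binocular_ratio = ratio,
                 gabor_left = NULL, gabor_right = NULL,
                 valid = NA, rejection = NULL, index = index),
            class = "binocular_component")
}

#' @export
print.binocular_component <- function(x, ...) {
  cat(sprintf("binocular_component: E_l %.3g, E_r %.3g, ratio %.3f, valid: %s\n",
              x$left_energy, x$right_energy, x$binocular_ratio,
              format(x$valid)))
  invisible(x)
}

#' Amari index between an estimated unmixing and a true mixing matrix
#'
#' Permutation- and scale-invariant distance on `P = |W A|`, normalized
#' to `[0, 1]`; 0 means `W A` is a signed scaled permutation, i.e.
#' perfect source recovery.
#'
#' @param w Estimated unmixing matrix (sources-from-data, `k x k`).
#' @param a True mixing matrix (`k x k`).
#' @return Scalar in `[0, 1]`.
#' @export
amari_index <- function(w, a) {
  p <- abs(w %*% a)
  k <- nrow(p)
  r1 <- sum(rowSums(p) / apply(p, 1, max) - 1)
  r2 <- sum(colSums(p) / apply(p, 2, max) - 1)
  (r1 + r2) / (2 * k * (k - 1))
}

#' Arrange pixel-space filters as a viewable mosaic
#'
#' Lays the binocular filters out on a grid (left|right halves side by
#' side per component, one-pixel separators), each filter scaled
#' symmetrically about zero — a quick visual check of the learned
#' components, writable with [write_pgm()].
#'
#' @param model An [fit_ica()] model with filters attached.
#' @param ncol Number of components per mosaic row.
#' @return A numeric matrix in `[-1, 1]`.
#' @export
component_mosaic <- function(model, ncol = 8) {
  stopifnot(!is.null(model$filters))
  w <- model$patch_width
  k <- nrow(model$filters)
  nrow_m <- ceiling(k / ncol)
  tile_h <- w + 1; tile_w <- 2 * w + 2
  out <- matrix(0, nrow_m * tile_h + 1, ncol * tile_w + 1)
  for (i in seq_len(k)) {
    comp <- split_component(model, i)
    tile <- cbind(comp$left_weights, comp$right_weights)
    tile <- tile / max(abs(tile))
    r <- (ceiling(i / ncol) - 1) * tile_h + 1
    c <- ((i - 1) %% ncol) * tile_w + 1
    out[r + seq_len(w), c + seq_len(2 * w)] <- tile
  }
  out
}
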