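# Patch normalisation (per-eye centring/scaling, joint renormalisation)
# and truncated PCA whitening.

#' Centre and normalise one binocular patch
#'
#' Per eye the patch is centred (its mean subtracted) and divided by the
#' magnitude of the centred patch, so each eye is exactly unit-norm; the
#' two halves are then concatenated and the concatenation divided by its
#' own magnitude, so the output is a unit vector. The result is invariant
#' to affine luminance rescalings `a*x + b` (a > 0) applied per eye.
#'
#' The `denominator = "raw"` option divides each eye by the magnitude of
#' the *un-centred* patch instead (a literal reading of the per-eye
#' normalisation that is not scale-invariant); the default `"centred"`
#' reading is used throughout the package.
#'
#' @param left,right Numeric vectors (vectorized per-eye patches).
#' @param denominator `"centred"` (default) or `"raw"`.
#' @return Unit-norm numeric vector of length
#'   `length(left) + length(right)`, or `NULL` for a degenerate (flat)
#'   patch in either eye.
#' @examples
#' normalize_binocular_patch(c(0, 2), c(1, 3))  # (-1/2, 1/2, -1/2, 1/2)
#' @export
normalize_binocular_patch <- function(left, right,
                                      denominator = c("centred", "raw")) {
  denominator <- match.arg(denominator)
  x <- normalize_patch_matrix(matrix(c(left, right), 1), length(left),
                              denominator)
  if (nrow(x$data) == 0) NULL else drop(x$data)
}

# Vectorized worker: X is n x (dl + dr); returns list(data, dropped).
normalize_patch_matrix <- function(x, dl, denominator = "centred",
                                   tol = 1e-12) {
  n <- nrow(x)
  lh <- x[, seq_len(dl), drop = FALSE]
  rh <- x[, -seq_len(dl), drop = FALSE]
  norm_eye <- function(m) {
    mu <- rowMeans(m)
    mc <- m - mu
    mag <- if (denominator == "centred") sqrt(rowSums(mc^2))
           else sqrt(rowSums(m^2))
    list(x = mc / mag, degenerate = sqrt(rowSums(mc^2)) < tol | mag < tol)
  }
  nl <- norm_eye(lh); nr <- norm_eye(rh)
  bad <- nl$degenerate | nr$degenerate
  out <- cbind(nl$x, nr$x)[!bad, , drop = FALSE]
  out <- out / sqrt(rowSums(out^2))
  list(data = out, dropped = which(bad))
}

#' Normalise every patch of a patch set
#'
#' Applies [normalize_binocular_patch()] row-wise; degenerate (flat)
#' patches are dropped and their indices recorded in the `dropped`
#' attribute of the result.
#'
#' @param ps A patch set from [sample_patches()].
#' @inheritParams normalize_binocular_patch
#' @return The patch set with unit-norm rows; dropped row indices in
#'   `attr(, "dropped")`.
#' @export
normalize_patchset <- function(ps, denominator = c("centred", "raw")) {
  denominator <- match.arg(denominator)
  res <- normalize_patch_matrix(ps$data, ps$geometry$width^2, denominator)
  if (length(res$dropped) > 0) {
    message(sprintf("dropped %d degenerate (flat) patches",
                    length(res$dropped)))
    ps$positions <- ps$positions[-res$dropped, , drop = FALSE]
  }
  ps$data <- res$data
  attr(ps, "dropped") <- res$dropped
  ps
}

#' Fit a truncated PCA whitening transform
#'
#' Principal component analysis of the (ensemble-centred) patch matrix,
#' truncated to the `K` HIGHEST-variance axes — truncation discards the
#' low-variance, high-spatial-frequency axes that are dominated by noise.
#' The forward transform ([whiten()]) projects onto the retained axes and
#' scales each to unit variance, so the training-set covariance of the
#' output is the identity.
#'
#' @param x Numeric matrix (`n x d`, patches in rows) or a patch set.
#' @param k Number of components to retain; default 250.
#' @return An object of class `whitening_model`: `mean`, `axes`
#'   (`d x k`, orthonormal), `sdev` (per-axis standard deviations),
#'   `k`, `variance_fraction` retained.
#' @export
fit_whitening <- function(x, k = 250) {
  if (inherits(x, "patch_set")) x <- x$data
  n <- nrow(x); d <- ncol(x)
  if (n <= k)
    stop(sprintf("need more patches (%d) than retained components (%d)", n, k))
  if (k > d) stop("k exceeds the patch dimensionality")
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  cv <- crossprod(xc) / (n - 1)
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  rank <- sum(ev > max(ev) * 1e-12)
  if (rank < k)
    stop(sprintf("data rank %d is below the requested %d components", rank, k))
  structure(list(mean = mu, axes = eg$vectors[, seq_len(k), drop = FALSE],
                 sdev = sqrt(ev[seq_len(k)]), k = k,
                 variance_fraction = sum(ev[seq_len(k)]) / sum(ev)),
            class = "whitening_model")
}

#' @export
print.whitening_model <- function(x, ...) {
  cat(sprintf("whitening_model: %d -> %d axes, %.1f%% variance retained\n",
              length(x$mean), x$k, 100 * x$variance_fraction))
  invisible(x)
}

#' Apply a whitening transform
#'
#' @param model A [fit_whitening()] model.
#' @param x Matrix (`n x d`) or patch set; dimensions must match the
#'   model.
#' @return `n x k` matrix with (approximately) identity covariance on the
#'   training set.
#' @export
whiten <- function(model, x) {
  if (inherits(x, "patch_set")) x <- x$data
  if (is.null(dim(x))) x <- matrix(x, 1)
  if (ncol(x) != length(model$mean))
    stop("dimension mismatch between data and whitening model")
  sweep(sweep(x, 2, model$mean) %*% model$axes, 2, model$sdev, "/")
}

#' Map a whitened-space filter to pixel space
#'
#' Composes an ICA filter (a row of the unmixing matrix, acting on
#' whitened vectors) with the whitening transform so that the returned
#' vector acts directly on raw normalized patches:
#' `filter . (x - mean) == w . whiten(x)` for every patch `x`.
#'
#' @param model A [fit_whitening()] model.
#' @param w Length-`k` filter in whitened space (or a matrix of filters
#'   in rows).
#' @return Pixel-space filter(s): length-`d` vector or `m x d` matrix.
#' @export
unwhiten_filter <- function(model, w) {
  if (is.null(dim(w))) {
    if (length(w) != model$k) stop("filter length must equal model k")
    drop(model$axes %*% (w / model$sdev))
  } else {
    if (ncol(w) != model$k) stop("filter width must equal model k")
    t(model$axes %*% t(sweep(w, 2, model$sdev, "/")))
  }
}
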