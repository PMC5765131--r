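# 2-D Gabor model: evaluation, canonical parameter form, and a
# deterministic nonlinear least-squares fitter for per-eye component
# halves.

#' Gabor parameter set
#'
#' A 2-D Gabor is the product of an oriented Gaussian window and an
#' oriented sinusoidal carrier:
#' `g = A * exp(-xr^2/(2*sigma_w^2) - yr^2/(2*sigma_h^2)) * cos(2*pi*f*z + phi)`
#' where `(xr, yr)` are the envelope-rotated (by `psi`), centre-shifted
#' coordinates and `z = dx*cos(theta) - dy*sin(theta)` is the carrier
#' coordinate, also measured from the envelope centre — so the phase
#' `phi` is relative to the envelope centre, as required for phase
#' disparity. Carrier orientation `theta` and envelope orientation `psi`
#' are independent.
#'
#' @param theta Carrier orientation, radians; canonical range `[0, pi)`.
#' @param f Carrier frequency, cycles/sample, in `(0, 0.5]`.
#' @param phi Carrier phase at the envelope centre, radians; canonical
#'   `[0, 2*pi)`.
#' @param sigma_w,sigma_h Envelope width and height (samples, > 0).
#' @param psi Envelope orientation, radians; canonical `[0, pi)`.
#' @param centre_x,centre_y Envelope centre relative to the patch centre,
#'   samples (x positive rightward, y positive upward).
#' @param amplitude Peak amplitude, `>= 0` (negative inputs are folded
#'   into the phase).
#' @param fit_error Normalized residual of a fit in `[0, 1]`; `NA` for a
#'   constructed parameter set.
#' @return An object of class `gabor_params` in canonical form.
#' @export
gabor_params <- function(theta, f, phi, sigma_w, sigma_h, psi = theta,
                         centre_x = 0, centre_y = 0, amplitude = 1,
                         fit_error = NA_real_) {
  stopifnot(f > 0, sigma_w > 0, sigma_h > 0)
  p <- structure(list(theta = theta, f = f, phi = phi,
                      sigma_w = sigma_w, sigma_h = sigma_h, psi = psi,
                      centre_x = centre_x, centre_y = centre_y,
                      amplitude = amplitude, fit_error = fit_error),
                 class = "gabor_params")
  canonicalize_gabor(p)
}

#' @export
print.gabor_params <- function(x, ...) {
  cat(sprintf(
    "gabor_params: theta %.3f, f %.4f c/sample, phi %.3f, sigma (%.2f, %.2f), psi %.3f, centre (%.2f, %.2f), A %.3g, err %.3f\n",
    x$theta, x$f, x$phi, x$sigma_w, x$sigma_h, x$psi,
    x$centre_x, x$centre_y, x$amplitude, x$fit_error))
  invisible(x)
}

#' Canonicalize Gabor parameters
#'
#' Maps an arbitrary parameter set onto the canonical ranges without
#' changing the described surface: `amplitude >= 0` (negative amplitude
#' folds into `phi + pi`), `theta` in `[0, pi)` (a `pi` shift of the
#' carrier orientation negates the carrier coordinate, so `phi -> -phi`),
#' `psi` in `[0, pi)` (the envelope is symmetric under `psi + pi`), and
#' `phi` in `[0, 2*pi)`.
#'
#' @param p A `gabor_params` (or plain list with the same fields).
#' @return A canonical `gabor_params`.
#' @export
canonicalize_gabor <- function(p) {
  if (p$amplitude < 0) {
    p$amplitude <- -p$amplitude
    p$phi <- p$phi + pi
  }
  p$sigma_w <- abs(p$sigma_w); p$sigma_h <- abs(p$sigma_h)
  # theta -> theta - k*pi flips the carrier coordinate k times
  k <- floor(p$theta / pi)
  p$theta <- p$theta - k * pi
  if (k %% 2 == 1) p$phi <- -p$phi
  p$psi <- p$psi %% pi
  p$phi <- p$phi %% (2 * pi)
  class(p) <- "gabor_params"
  p
}

#' Evaluate a Gabor surface
#'
#' @param params A [gabor_params()].
#' @param x,y Sample coordinates (x positive rightward, y positive
#'   upward, origin at the patch centre); any shape, evaluated
#'   elementwise.
#' @return Gabor values, same shape as `x`.
#' @examples
#' p <- gabor_params(theta = 0, f = 0.125, phi = 0, sigma_w = 3, sigma_h = 3)
#' eval_gabor(p, 4, 0)  # cos(pi) * exp(-16/18) = -0.4111
#' @export
eval_gabor <- function(params, x, y) {
  dx <- x - params$centre_x
  dy <- y - params$centre_y
  xr <- dx * cos(params$psi) - dy * sin(params$psi)
  yr <- dx * sin(params$psi) + dy * cos(params$psi)
  z <- dx * cos(params$theta) - dy * sin(params$theta)
  params$amplitude *
    exp(-xr^2 / (2 * params$sigma_w^2) - yr^2 / (2 * params$sigma_h^2)) *
    cos(2 * pi * params$f * z + params$phi)
}

# Integer sample grid of an n x n patch: x per column (rightward),
# y per row (row 1 = top = most positive y).
gabor_grid <- function(n) {
  xs <- (0:(n - 1)) - floor(n / 2)
  list(x = xs, y = rev(xs))
}

#' Acceptance thresholds for Gabor fits
#'
#' @param max_residual Largest acceptable normalized residual; default
#'   0.5 (the fit must explain at least three quarters of the energy).
#' @param sigma_range Admissible envelope sigma range in samples,
#'   relative bounds applied as `[sigma_range[1], sigma_range[2] * n]`
#'   with `n` the patch side; default `c(0.5, 1)`.
#' @param centre_factor Envelope centre must lie within
#'   `centre_factor * n/2` samples of the patch centre; default 1.5.
#' @return List of thresholds.
#' @export
gabor_accept_config <- function(max_residual = 0.5,
                                sigma_range = c(0.5, 1),
                                centre_factor = 1.5) {
  list(max_residual = max_residual, sigma_range = sigma_range,
       centre_factor = centre_factor)
}

gabor_failure <- function(reason) {
  structure(list(reason = reason), class = "gabor_fit_failure")
}

#' Test whether a Gabor fit failed
#' @param x Result of [fit_gabor()].
#' @return Logical.
#' @export
is_gabor_failure <- function(x) inherits(x, "gabor_fit_failure")

# Deterministic initialization: dominant Fourier peak -> (theta, f),
# energy moments -> (centre, sigmas, psi).
gabor_init <- function(patch) {
  n <- nrow(patch)
  g <- gabor_grid(n)
  fm <- stats::fft(patch)
  a <- Mod(fm)
  a[1, 1] <- 0
  peak <- arrayInd(which.max(a), dim(a))
  tofreq <- function(k) {
    f <- (k - 1) / n
    ifelse(f > 0.5, f - 1, f)
  }
  fi <- tofreq(peak[1]); fj <- tofreq(peak[2])
  # x-frequency follows the column index; row index runs OPPOSITE to y
  fx <- fj; fy <- -fi
  if (fx < 0 || (fx == 0 && fy < 0)) { fx <- -fx; fy <- -fy }
  f0 <- min(max(sqrt(fx^2 + fy^2), 0.03), 0.45)
  theta0 <- atan2(-fy, fx) %% pi

  wts <- patch^2
  wts <- wts / sum(wts)
  xm <- matrix(g$x, n, n, byrow = TRUE)
  ym <- matrix(g$y, n, n)
  cx <- sum(wts * xm); cy <- sum(wts * ym)
  vxx <- sum(wts * (xm - cx)^2); vyy <- sum(wts * (ym - cy)^2)
  vxy <- sum(wts * (xm - cx) * (ym - cy))
  ec <- eigen(matrix(c(vxx, vxy, vxy, vyy), 2, 2), symmetric = TRUE)
  # |g|^2 halves the variance of the envelope; the cos^2 ripple inflates
  # it a little along the carrier — good enough for a starting point
  s1 <- sqrt(2 * max(ec$values[1], 0.25))
  s2 <- sqrt(2 * max(ec$values[2], 0.25))
  psi0 <- (atan2(ec$vectors[2, 1], ec$vectors[1, 1])) %% pi
  # psi rotates (x,y) so that xr follows sigma_w: the principal axis of
  # the energy ellipse corresponds to rotation by -psi
  list(theta = theta0, f = f0, cx = cx, cy = cy,
       sigma_w = min(s1, n), sigma_h = min(s2, n), psi = (-psi0) %% pi)
}

#' Fit a Gabor function to a square patch
#'
#' Deterministic nonlinear least squares: the carrier orientation and
#' frequency are initialized from the dominant 2-D Fourier peak, the
#' envelope centre and sigmas from the energy moments of the patch, and
#' the phase from a grid of 8 candidate phases (each scored with its
#' closed-form optimal amplitude); box-constrained quasi-Newton
#' refinement (`optim` L-BFGS-B) then polishes all nine parameters. A
#' second start from the runner-up phase is tried when the first result
#' does not meet the acceptance thresholds.
#'
#' @param patch Square numeric matrix, side `>= 8`, row 1 = top.
#' @param accept A [gabor_accept_config()].
#' @return A canonical [gabor_params()] with `fit_error` set, or a
#'   `gabor_fit_failure` (see [is_gabor_failure()]) with a `reason`
#'   (`"degenerate"`, `"no-fit"`, or `"rejected"`).
#' @export
fit_gabor <- function(patch, accept = gabor_accept_config()) {
  if (!is.matrix(patch) || nrow(patch) != ncol(patch))
    stop("patch must be a square matrix")
  n <- nrow(patch)
  if (n < 8) stop("patch side must be at least 8 samples")
  energy <- sum(patch^2)
  if (energy < 1e-20 || stats::sd(patch) < 1e-12)
    return(gabor_failure("degenerate"))

  g <- gabor_grid(n)
  xm <- matrix(g$x, n, n, byrow = TRUE)
  ym <- matrix(g$y, n, n)
  init <- gabor_init(patch)

  unit_gabor <- function(par) {
    p <- list(theta = par[1], f = par[2], phi = par[3], sigma_w = par[4],
              sigma_h = par[5], psi = par[6], centre_x = par[7],
              centre_y = par[8], amplitude = 1)
    eval_gabor(p, xm, ym)
  }
  obj <- function(par) {
    gv <- par[9] * unit_gabor(par[1:8])
    sum((patch - gv)^2)
  }
  grad <- function(par) {
    theta <- par[1]; f <- par[2]; phi <- par[3]
    sw <- par[4]; sh <- par[5]; psi <- par[6]
    dx <- xm - par[7]; dy <- ym - par[8]; a <- par[9]
    xr <- dx * cos(psi) - dy * sin(psi)
    yr <- dx * sin(psi) + dy * cos(psi)
    z <- dx * cos(theta) - dy * sin(theta)
    e <- exp(-xr^2 / (2 * sw^2) - yr^2 / (2 * sh^2))
    arg <- 2 * pi * f * z + phi
    cv <- cos(arg); sv <- sin(arg)
    r2 <- -2 * (patch - a * e * cv)  # d(SSE)/d(g)
    aes <- a * e * sv
    d <- c(
      theta = sum(r2 * (-aes * 2 * pi * f * (-dx * sin(theta) - dy * cos(theta)))),
      f = sum(r2 * (-aes * 2 * pi * z)),
      phi = sum(r2 * (-aes)),
      sw = sum(r2 * a * e * cv * xr^2 / sw^3),
      sh = sum(r2 * a * e * cv * yr^2 / sh^3),
      psi = sum(r2 * a * cv * e * xr * yr * (1 / sw^2 - 1 / sh^2)),
      cx = sum(r2 * (a * cv * e * (xr * cos(psi) / sw^2 + yr * sin(psi) / sh^2) +
                       aes * 2 * pi * f * cos(theta))),
      cy = sum(r2 * (a * cv * e * (-xr * sin(psi) / sw^2 + yr * cos(psi) / sh^2) -
                       aes * 2 * pi * f * sin(theta))),
      a = sum(r2 * e * cv))
    unname(d)
  }

  phis <- (0:7) * pi / 4
  scores <- vapply(phis, function(phi) {
    gv <- unit_gabor(c(init$theta, init$f, phi, init$sigma_w,
                       init$sigma_h, init$psi, init$cx, init$cy))
    denom <- sum(gv^2)
    a <- if (denom > 0) sum(patch * gv) / denom else 0
    sum((patch - a * gv)^2)
  }, numeric(1))
  ord <- order(scores)

  lower <- c(-2 * pi, 0.02, -2 * pi, 0.3, 0.3, -2 * pi,
             -0.75 * n, -0.75 * n, 1e-8)
  upper <- c(4 * pi, 0.5, 4 * pi, n, n, 4 * pi,
             0.75 * n, 0.75 * n, Inf)

  run_start <- function(phi) {
    gv <- unit_gabor(c(init$theta, init$f, phi, init$sigma_w,
                       init$sigma_h, init$psi, init$cx, init$cy))
    a0 <- sum(patch * gv) / max(sum(gv^2), 1e-12)
    if (abs(a0) < 1e-10) a0 <- sqrt(energy / (n * n))
    par0 <- c(init$theta, init$f, phi, init$sigma_w, init$sigma_h,
              init$psi, init$cx, init$cy, abs(a0))
    if (a0 < 0) par0[3] <- phi + pi
    tryCatch(
      stats::optim(par0, obj, gr = grad, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 400, factr = 1e8)),
      error = function(e) NULL)
  }

  check <- function(fit) {
    if (is.null(fit)) return(NULL)
    par <- fit$par
    p <- canonicalize_gabor(structure(
      list(theta = par[1], f = par[2], phi = par[3], sigma_w = par[4],
           sigma_h = par[5], psi = par[6], centre_x = par[7],
           centre_y = par[8], amplitude = par[9],
           fit_error = min(sqrt(fit$value / energy), 1)),
      class = "gabor_params"))
    p
  }
  admissible <- function(p) {
    !is.null(p) &&
      p$fit_error <= accept$max_residual &&
      p$sigma_w >= accept$sigma_range[1] &&
      p$sigma_h >= accept$sigma_range[1] &&
      p$sigma_w <= accept$sigma_range[2] * n &&
      p$sigma_h <= accept$sigma_range[2] * n &&
      abs(p$centre_x) <= accept$centre_factor * n / 2 &&
      abs(p$centre_y) <= accept$centre_factor * n / 2 &&
      p$f <= 0.5
  }

  best <- check(run_start(phis[ord[1]]))
  if (!admissible(best)) {
    second <- check(run_start(phis[ord[2]]))
    if (!is.null(second) &&
        (is.null(best) || second$fit_error < best$fit_error))
      best <- second
  }
  if (is.null(best)) return(gabor_failure("no-fit"))
  if (!admissible(best)) return(gabor_failure("rejected"))
  best
}

#' Fit Gabor functions to both eyes of a binocular component
#'
#' Fits [fit_gabor()] independently to the left and right halves. The
#' component is `valid` iff both fits succeed AND the binocular energy
#' ratio meets the threshold; the reason for any rejection is recorded.
#' The binocular ratio itself is computed from the raw filter weights in
#' [split_component()] and is never touched here.
#'
#' @param component A [split_component()] result.
#' @param accept A [gabor_accept_config()].
#' @param ratio_threshold Binocular-ratio threshold for validity;
#'   default 0.25.
#' @return The component with `gabor_left`, `gabor_right`, `valid` and
#'   `rejection` filled in.
#' @export
fit_component <- function(component, accept = gabor_accept_config(),
                          ratio_threshold = 0.25) {
  gl <- tryCatch(fit_gabor(component$left_weights, accept),
                 error = function(e) gabor_failure("no-fit"))
  gr <- tryCatch(fit_gabor(component$right_weights, accept),
                 error = function(e) gabor_failure("no-fit"))
  component$gabor_left <- gl
  component$gabor_right <- gr
  reasons <- character()
  if (is_gabor_failure(gl)) reasons <- c(reasons, paste0("left:", gl$reason))
  if (is_gabor_failure(gr)) reasons <- c(reasons, paste0("right:", gr$reason))
  if (component$binocular_ratio < ratio_threshold)
    reasons <- c(reasons, "monocular")
  component$valid <- length(reasons) == 0
  component$rejection <- if (length(reasons)) paste(reasons, collapse = ";")
                         else NA_character_
  component
}
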