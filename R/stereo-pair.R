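# Binocular image pair container and plain-text raster IO.

#' Binocular image pair
#'
#' A pair of co-registered left/right luminance rasters with angular
#' calibration. Images are stored as numeric matrices with row 1 at the
#' TOP of the image; the accompanying `azimuth` (per column, positive
#' rightward) and `elevation` (per row, positive upward) vectors give the
#' visual-angle coordinates of every sample relative to fixation, in
#' arcmin.
#'
#' @param left,right Numeric matrices of identical dimensions.
#' @param pitch Angular sample spacing, arcmin per sample.
#' @param azimuth,elevation Optional coordinate vectors (arcmin); derived
#'   from `pitch` with fixation at the raster centre when omitted.
#' @param margin Width (arcmin) of a border band whose pixels may be
#'   contaminated (e.g. by warping off the raster edge); patch sampling
#'   avoids it.
#' @return An object of class `stereo_pair`.
#' @export
stereo_pair <- function(left, right, pitch, azimuth = NULL,
                        elevation = NULL, margin = 0) {
  stopifnot(is.matrix(left), is.matrix(right),
            all(dim(left) == dim(right)), pitch > 0, margin >= 0)
  nr <- nrow(left); nc <- ncol(left)
  if (is.null(azimuth))
    azimuth <- (seq_len(nc) - (nc + 1) / 2) * pitch
  if (is.null(elevation))
    elevation <- ((nr + 1) / 2 - seq_len(nr)) * pitch
  stopifnot(length(azimuth) == nc, length(elevation) == nr)
  structure(list(left = left, right = right, pitch = pitch,
                 azimuth = azimuth, elevation = elevation,
                 margin = margin),
            class = "stereo_pair")
}

#' @export
print.stereo_pair <- function(x, ...) {
  cat(sprintf(
    "stereo_pair: %d x %d samples @ %g arcmin/sample, azimuth [%g, %g], elevation [%g, %g]\n",
    nrow(x$left), ncol(x$left), x$pitch,
    min(x$azimuth), max(x$azimuth), min(x$elevation), max(x$elevation)))
  invisible(x)
}

#' Ground-truth disparity field
#'
#' Horizontal and vertical disparity maps (arcmin) on the same raster as
#' the texture they were rendered from. Positive horizontal disparity is
#' uncrossed/far; positive vertical disparity means the feature projects
#' higher in the left image.
#'
#' @param horizontal,vertical Numeric matrices of equal dimensions.
#' @return An object of class `disparity_field`.
#' @export
disparity_field <- function(horizontal, vertical) {
  stopifnot(is.matrix(horizontal), is.matrix(vertical),
            all(dim(horizontal) == dim(vertical)))
  structure(list(horizontal = horizontal, vertical = vertical),
            class = "disparity_field")
}

# ---- plain-text raster IO (16-bit ASCII PGM, P2) -------------------------

#' Write a luminance raster as 16-bit ASCII PGM
#'
#' The image is affinely mapped onto 0..65535; the scaling is recoverable
#' from the JSON sidecars written by [write_stereo_pair()].
#'
#' @param image Numeric matrix, row 1 = image top.
#' @param path Output file path.
#' @return Invisibly, `c(offset, scale)` of the applied mapping
#'   (`code = round((value - offset) * scale)`).
#' @export
write_pgm <- function(image, path) {
  rng <- range(image)
  scale <- if (diff(rng) > 0) 65535 / diff(rng) else 1
  code <- round((image - rng[1]) * scale)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(image), nrow(image)), "65535"), con)
  write(t(code), file = con, ncolumns = ncol(image))
  invisible(c(offset = rng[1], scale = scale))
}

#' Read a 16-bit ASCII PGM written by [write_pgm()]
#'
#' @param path File path.
#' @param offset,scale Optional inverse mapping (as returned by
#'   [write_pgm()]); identity when omitted.
#' @return Numeric matrix.
#' @export
read_pgm <- function(path, offset = 0, scale = 1) {
  txt <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (txt[1] != "P2") stop("only ASCII PGM (P2) is supported")
  nc <- as.integer(txt[2]); nr <- as.integer(txt[3])
  vals <- as.numeric(txt[-(1:4)])
  stopifnot(length(vals) == nr * nc)
  matrix(vals, nrow = nr, ncol = nc, byrow = TRUE) / scale + offset
}

#' Write a stereo pair to disk
#'
#' Writes `<prefix>_L.pgm` / `<prefix>_R.pgm` plus a `<prefix>.json`
#' sidecar recording the angular calibration and the PGM intensity
#' mappings.
#'
#' @param pair A [stereo_pair()].
#' @param prefix Path prefix (no extension).
#' @param extra Optional named list merged into the sidecar (e.g. seeds).
#' @return Invisibly, the sidecar path.
#' @export
write_stereo_pair <- function(pair, prefix, extra = list()) {
  ml <- write_pgm(pair$left, paste0(prefix, "_L.pgm"))
  mr <- write_pgm(pair$right, paste0(prefix, "_R.pgm"))
  meta <- c(list(pitch = pair$pitch, margin = pair$margin,
                 n_rows = nrow(pair$left), n_cols = ncol(pair$left),
                 azimuth_first = pair$azimuth[1],
                 elevation_first = pair$elevation[1],
                 left_map = as.list(ml), right_map = as.list(mr)),
            extra)
  side <- paste0(prefix, ".json")
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' Read a stereo pair written by [write_stereo_pair()]
#'
#' @param prefix Path prefix used when writing.
#' @return A [stereo_pair()].
#' @export
read_stereo_pair <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  left <- read_pgm(paste0(prefix, "_L.pgm"),
                   meta$left_map$offset, meta$left_map$scale)
  right <- read_pgm(paste0(prefix, "_R.pgm"),
                    meta$right_map$offset, meta$right_map$scale)
  pitch <- meta$pitch
  nc <- meta$n_cols; nr <- meta$n_rows
  stereo_pair(left, right, pitch,
              azimuth = meta$azimuth_first + (seq_len(nc) - 1) * pitch,
              elevation = meta$elevation_first - (seq_len(nr) - 1) * pitch,
              margin = meta$margin)
}

#' Write a disparity field as tab-separated text with a JSON sidecar
#'
#' @param field A [disparity_field()].
#' @param prefix Path prefix; writes `<prefix>_dx.tsv`, `<prefix>_dy.tsv`
#'   and `<prefix>.json`.
#' @param extra Optional named list merged into the sidecar.
#' @return Invisibly, the sidecar path.
#' @export
write_disparity_field <- function(field, prefix, extra = list()) {
  utils::write.table(field$horizontal, paste0(prefix, "_dx.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(field$vertical, paste0(prefix, "_dy.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  meta <- c(list(n_rows = nrow(field$horizontal),
                 n_cols = ncol(field$horizontal), units = "arcmin"), extra)
  side <- paste0(prefix, ".json")
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}
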