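#' Construct a Gabor wavelet feature
#'
#' A Gabor wavelet is a sinusoidal grating windowed by an isotropic Gaussian
#' envelope. Position uses 0-based pixel coordinates (`x_px` = column,
#' `y_px` = row), with wavelet centers on pixel centers.
#'
#' @param x_px,y_px Center position in pixels (0-based column/row).
#' @param sf_cpd Spatial frequency of the carrier in cycles per degree of
#'   visual angle.
#' @param orientation_deg Grating orientation in degrees, in [0, 180).
#' @param phase_rad Carrier phase in radians, reduced modulo 2*pi.
#' @param sigma_px Gaussian envelope standard deviation in pixels. The
#'   default, half the carrier wavelength, gives roughly one octave of
#'   frequency bandwidth.
#' @param amplitude Unitless scale factor.
#' @param geom [image_geometry()] used for the wavelength default and the
#'   bounds check.
#' @return A one-row data.frame with columns `x_px`, `y_px`, `sf_cpd`,
#'   `orientation_deg`, `phase_rad`, `sigma_px`, `amplitude`.
#' @examples
#' w <- gabor_wavelet(125, 125, sf_cpd = 1, orientation_deg = 40)
#' img <- render_wavelet(w, image_geometry())
#' @export
gabor_wavelet <- function(x_px, y_px, sf_cpd, orientation_deg,
                          phase_rad = 0,
                          sigma_px = NULL,
                          amplitude = 1,
                          geom = image_geometry()) {
  assert_scalar_num(sf_cpd, "sf_cpd", lower = .Machine$double.eps)
  if (x_px < 0 || x_px >= geom$side_px || y_px < 0 || y_px >= geom$side_px)
    stopf("wavelet center (%s, %s) outside the %d px image", x_px, y_px,
          geom$side_px)
  if (is.null(sigma_px))
    sigma_px <- 0.5 * geom$px_per_dva / sf_cpd # half the wavelength in px
  data.frame(
    x_px = x_px, y_px = y_px, sf_cpd = sf_cpd,
    orientation_deg = orientation_deg %% 180,
    phase_rad = phase_rad %% (2 * pi),
    sigma_px = sigma_px, amplitude = amplitude
  )
}

# Windowed evaluation of one wavelet: values on a clipped square window of
# half-width `half` pixels around the center (default 6 sigma, where the
# envelope is below 1.6e-8 of its peak). Returns
# linear indices into the side_px x side_px matrix plus the values there;
# the wavelet is numerically negligible outside. Workhorse for feature
# sums, covariances and sparse regression designs.
gabor_window <- function(w, geom, half = NULL) {
  s <- geom$side_px
  if (is.null(half)) half <- ceiling(6 * w$sigma_px)
  cx <- w$x_px; cy <- w$y_px
  cols <- max(0, floor(cx - half)):min(s - 1, ceiling(cx + half))
  rows <- max(0, floor(cy - half)):min(s - 1, ceiling(cy + half))
  x <- outer(rep(1, length(rows)), cols) - cx
  y <- outer(rows, rep(1, length(cols))) - cy
  th <- w$orientation_deg * pi / 180
  xr <- x * cos(th) + y * sin(th)
  yr <- -x * sin(th) + y * cos(th)
  f_cpp <- w$sf_cpd / geom$px_per_dva
  vals <- w$amplitude * exp(-(xr^2 + yr^2) / (2 * w$sigma_px^2)) *
    cos(2 * pi * f_cpp * xr + w$phase_rad)
  idx <- outer(rows + 1L, cols * s, `+`) # linear index: row + col*side
  list(idx = as.integer(idx), vals = as.numeric(vals))
}

#' Render a Gabor wavelet as a full image
#'
#' Evaluates amplitude * exp(-(x'^2+y'^2)/(2 sigma^2)) * cos(2 pi f x' +
#' phase) over the pixel grid, where (x', y') are pixel offsets from the
#' center rotated by the orientation and f is the carrier frequency in
#' cycles per pixel (sf_cpd / px_per_dva).
#'
#' @param w A wavelet as returned by [gabor_wavelet()] (one row).
#' @param geom An [image_geometry()].
#' @return A `side_px` x `side_px` numeric matrix (rows = y, columns = x).
#' @export
render_wavelet <- function(w, geom = image_geometry()) {
  w <- as.list(w[1, , drop = FALSE])
  if (w$x_px < 0 || w$x_px >= geom$side_px || w$y_px < 0 ||
      w$y_px >= geom$side_px)
    stopf("wavelet center outside image")
  img <- matrix(0, geom$side_px, geom$side_px)
  win <- gabor_window(w, geom, half = geom$side_px) # full extent
  img[win$idx] <- win$vals
  img
}

#' Sum a subset of a feature bank into one image
#'
#' Pixel-wise sum of the rendered wavelets with the given feature ids; the
#' building block of partial image reconstructions. Additive over disjoint
#' id sets.
#'
#' @param bank A [feature_bank()].
#' @param ids Integer feature ids (subset of the bank's ids). The empty set
#'   yields an all-zero image.
#' @param geom Geometry; defaults to the bank's.
#' @return A numeric matrix of size `side_px` x `side_px`.
#' @export
sum_features <- function(bank, ids, geom = bank$geometry) {
  ids <- as.integer(ids)
  pos <- match(ids, bank$wavelets$feature_id)
  if (anyNA(pos))
    stopf("unknown feature id(s): %s",
          paste(ids[is.na(pos)][seq_len(min(5, sum(is.na(pos))))], collapse = ", "))
  img <- matrix(0, geom$side_px, geom$side_px)
  for (p in pos) {
    win <- gabor_window(as.list(bank$wavelets[p, ]), geom)
    img[win$idx] <- img[win$idx] + win$vals
  }
  img
}

#' Rescale a real-valued image to the full 8-bit display range
#'
#' Affine map sending the minimum to 0 and the maximum to 255, rounded to
#' integers with round-half-to-even (so a midpoint value of 127.5 becomes
#' 128). Pixel intensity order is preserved.
#'
#' @param img Numeric matrix; must not be constant.
#' @return Integer matrix with values in 0..255, min 0 and max 255.
#' @export
rescale_to_display <- function(img) {
  rng <- range(img)
  if (!all(is.finite(rng))) stopf("image contains non-finite values")
  if (rng[1] == rng[2])
    stopf("constant image cannot be rescaled to the 0-255 range")
  out <- round((img - rng[1]) / (rng[2] - rng[1]) * 255)
  storage.mode(out) <- "integer"
  out
}

#' Construct a feature bank
#'
#' The set of Gabor wavelets selected for one image, with dense integer
#' feature ids `0..n-1` and shared geometry. Banks produced by
#' [decompose()] carry equal amplitudes and a `covariance` column giving
#' each feature's sample covariance with the original image (the selection
#' score).
#'
#' @param image_id Identifier (character scalar).
#' @param wavelets Data.frame with at least the columns of
#'   [gabor_wavelet()]; a `feature_id` column is added (0-based, row order)
#'   if absent.
#' @param geometry An [image_geometry()].
#' @return An object of class `feature_bank` with fields `image_id`,
#'   `geometry`, `wavelets`, `n_features`.
#' @export
feature_bank <- function(image_id, wavelets, geometry = image_geometry()) {
  req <- c("x_px", "y_px", "sf_cpd", "orientation_deg", "phase_rad",
           "sigma_px", "amplitude")
  if (!all(req %in% names(wavelets)))
    stopf("wavelets must have columns: %s", paste(req, collapse = ", "))
  if (!"feature_id" %in% names(wavelets))
    wavelets$feature_id <- seq_len(nrow(wavelets)) - 1L
  wavelets$feature_id <- as.integer(wavelets$feature_id)
  if (anyDuplicated(wavelets$feature_id) ||
      !setequal(wavelets$feature_id, seq_len(nrow(wavelets)) - 1L))
    stopf("feature ids must be unique and dense 0..n-1")
  if (any(wavelets$x_px < 0 | wavelets$x_px >= geometry$side_px |
          wavelets$y_px < 0 | wavelets$y_px >= geometry$side_px))
    stopf("all wavelet centers must lie inside the image")
  front <- c("feature_id", req)
  wavelets <- wavelets[c(front, setdiff(names(wavelets), front))]
  rownames(wavelets) <- NULL
  structure(
    list(image_id = as.character(image_id), geometry = geometry,
         wavelets = wavelets, n_features = nrow(wavelets)),
    class = "feature_bank"
  )
}

#' @export
print.feature_bank <- function(x, ...) {
  cat(sprintf("<feature_bank> image '%s': %d wavelets, sf %.3g-%.3g cpd, %d px\n",
              x$image_id, x$n_features, min(x$wavelets$sf_cpd),
              max(x$wavelets$sf_cpd), x$geometry$side_px))
  invisible(x)
}

#' Write / read a feature bank (CSV plus JSON geometry sidecar)
#'
#' The wavelet table is written as plain CSV; image id and geometry go to a
#' JSON sidecar at the same path with extension `.json`. Pixel coordinates
#' are 0-based column/row indices of pixel centers.
#'
#' @param bank A [feature_bank()].
#' @param path CSV file path.
#' @return `write_feature_bank` returns `path` invisibly;
#'   `read_feature_bank` returns the restored [feature_bank()].
#' @export
write_feature_bank <- function(bank, path) {
  utils::write.csv(bank$wavelets, path, row.names = FALSE)
  sidecar <- sub("\\.[^.]*$", ".json", path)
  jsonlite::write_json(
    list(image_id = bank$image_id,
         side_px = bank$geometry$side_px,
         extent_dva = bank$geometry$extent_dva,
         coordinate_convention = "0-based column (x) / row (y), pixel centers"),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_bank
#' @export
read_feature_bank <- function(path) {
  wavelets <- utils::read.csv(path)
  sidecar <- sub("\\.[^.]*$", ".json", path)
  if (!file.exists(sidecar)) stopf("geometry sidecar not found: %s", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  feature_bank(meta$image_id, wavelets,
               image_geometry(meta$side_px, meta$extent_dva))
}

#' Write / read an 8-bit grayscale PNG
#'
#' @param img Integer matrix with values in 0..255 (see
#'   [rescale_to_display()]).
#' @param path PNG file path.
#' @return `write_image_png` returns `path` invisibly; `read_image_png`
#'   returns a matrix with values in 0..255.
#' @export
write_image_png <- function(img, path) {
  if (min(img) < 0 || max(img) > 255) stopf("image values must be in 0..255")
  png::writePNG(img / 255, path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1] # grayscale stored with channels
  round(a * 255)
}
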