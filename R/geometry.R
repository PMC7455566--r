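#' Image geometry: pixels and degrees of visual angle
#'
#' Describes a square stimulus image: its side length in pixels and the
#' visual angle it spans, from which the pixels-per-degree conversion is
#' derived. The defaults match a 250 x 250 pixel image spanning
#' 22.5 x 22.5 degrees of visual angle (about 11.11 px/dva).
#'
#' @param side_px Side length in pixels (positive integer).
#' @param extent_dva Visual angle spanned by the image, in degrees.
#' @return An object of class `image_geometry` with fields `side_px`,
#'   `extent_dva` and the derived `px_per_dva`.
#' @examples
#' geom <- image_geometry()
#' geom$px_per_dva # ~11.11
#' @export
image_geometry <- function(side_px = 250L, extent_dva = 22.5) {
  assert_scalar_num(side_px, "side_px", lower = 1)
  assert_scalar_num(extent_dva, "extent_dva", lower = .Machine$double.eps)
  structure(
    list(side_px = as.integer(side_px), extent_dva = extent_dva,
         px_per_dva = side_px / extent_dva),
    class = "image_geometry"
  )
}

#' @export
print.image_geometry <- function(x, ...) {
  cat(sprintf("<image_geometry> %d x %d px, %.3g dva (%.4g px/dva)\n",
              x$side_px, x$side_px, x$extent_dva, x$px_per_dva))
  invisible(x)
}

#' Spatial-frequency ladder configuration
#'
#' The wavelet dictionary uses a geometric ladder of spatial frequencies,
#' sf(n) = base * growth^n for n = 1..n_levels, together with a power-law
#' rule for how many wavelets are sampled per frequency,
#' nw(sf) = nw_scale * sf^nw_exponent, and a fixed set of equidistant
#' grating orientations covering [0, 180) degrees. The defaults give 29
#' frequencies between 0.24 and 2.07 cycles per degree of visual angle,
#' 21 wavelets sampled at the lowest frequency and 1008 at the highest,
#' and 18 orientations (0-170 in steps of 10).
#'
#' @param n_levels Number of ladder levels.
#' @param base,growth Geometric ladder parameters (`growth > 1`).
#' @param nw_scale,nw_exponent Power-law parameters of the per-frequency
#'   wavelet count rule.
#' @param n_orientations Number of equidistant orientations in [0, 180).
#' @return An object of class `ladder_config`.
#' @examples
#' cfg <- ladder_config()
#' ladder_sf(c(1, 29), cfg)
#' @export
ladder_config <- function(n_levels = 29L, base = 10 / 45, growth = 1.08,
                          nw_scale = 272, nw_exponent = 1.8,
                          n_orientations = 18L) {
  assert_scalar_num(n_levels, "n_levels", lower = 1)
  assert_scalar_num(base, "base", lower = .Machine$double.eps)
  if (!is.numeric(growth) || length(growth) != 1L || growth <= 1)
    stopf("`growth` must be > 1 (ascending ladder)")
  assert_scalar_num(nw_scale, "nw_scale", lower = .Machine$double.eps)
  assert_scalar_num(nw_exponent, "nw_exponent")
  assert_scalar_num(n_orientations, "n_orientations", lower = 1)
  structure(
    list(n_levels = as.integer(n_levels), base = base, growth = growth,
         nw_scale = nw_scale, nw_exponent = nw_exponent,
         n_orientations = as.integer(n_orientations)),
    class = "ladder_config"
  )
}

#' Orientations of a ladder configuration
#'
#' @param cfg A [ladder_config()].
#' @return Numeric vector of orientations in degrees, equidistant in
#'   [0, 180): with the default 18 orientations, 0, 10, ..., 170.
#' @export
ladder_orientations <- function(cfg = ladder_config()) {
  seq(0, 180 - 180 / cfg$n_orientations, length.out = cfg$n_orientations)
}

#' Spatial frequency at a ladder level
#'
#' Evaluates the geometric ladder sf(n) = base * growth^n. With the default
#' configuration the ladder runs from 0.24 (n = 1) to 2.07 (n = 29)
#' cycles/dva.
#'
#' @param n Level index (vectorized), each in `1..cfg$n_levels`.
#' @param cfg A [ladder_config()].
#' @return Spatial frequency in cycles per degree of visual angle.
#' @export
ladder_sf <- function(n, cfg = ladder_config()) {
  if (length(n) == 0 || anyNA(n) || any(n < 1 | n > cfg$n_levels) ||
      any(n != round(n)))
    stopf("ladder level `n` must be integer(s) in 1..%d", cfg$n_levels)
  cfg$base * cfg$growth^n
}

#' Number of wavelets sampled at a spatial frequency
#'
#' Evaluates the power-law sampling rule nw(sf) = nw_scale * sf^nw_exponent,
#' rounded to the nearest integer (round-half-to-even). With defaults this
#' yields 21 wavelets at 0.24 cycles/dva and 1008 at 2.07 cycles/dva.
#'
#' @param sf_cpd Spatial frequency in cycles/dva (vectorized, positive).
#' @param cfg A [ladder_config()].
#' @return Integer count(s) of wavelets to sample.
#' @export
features_per_sf <- function(sf_cpd, cfg = ladder_config()) {
  if (length(sf_cpd) == 0 || anyNA(sf_cpd) || any(sf_cpd <= 0))
    stopf("`sf_cpd` must be positive")
  as.integer(round(cfg$nw_scale * sf_cpd^cfg$nw_exponent))
}
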