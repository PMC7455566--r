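#' Synthetic feature bank
#'
#' Draws a random wavelet bank that mimics the frequency profile of a
#' decomposed image without requiring one: spatial frequencies are sampled
#' from the ladder with probability proportional to the per-frequency
#' sampling rule [features_per_sf()], positions are uniform over the image,
#' orientations uniform over the ladder orientations, phases uniform in
#' [0, 2*pi). A random positive `covariance` score column is attached
#' (descending), standing in for the covariance-with-original ranking of a
#' real decomposition.
#'
#' @param image_id Identifier.
#' @param n_features Bank size (default 1000).
#' @param geom An [image_geometry()].
#' @param ladder A [ladder_config()].
#' @param seed Optional integer seed.
#' @return A [feature_bank()] with a `covariance` column.
#' @export
synthetic_feature_bank <- function(image_id, n_features = 1000L,
                                   geom = image_geometry(),
                                   ladder = ladder_config(), seed = NULL) {
  with_seed(seed, {
    sfs <- ladder_sf(seq_len(ladder$n_levels), ladder)
    prob <- features_per_sf(sfs, ladder)
    sf <- sample(sfs, n_features, replace = TRUE, prob = prob)
    w <- data.frame(
      x_px = sample.int(geom$side_px, n_features, replace = TRUE) - 1L,
      y_px = sample.int(geom$side_px, n_features, replace = TRUE) - 1L,
      sf_cpd = sf,
      orientation_deg = sample(ladder_orientations(ladder), n_features,
                               replace = TRUE),
      phase_rad = stats::runif(n_features, 0, 2 * pi),
      sigma_px = 0.5 * geom$px_per_dva / sf,
      amplitude = 1,
      covariance = sort(stats::runif(n_features), decreasing = TRUE)
    )
    feature_bank(image_id, w, geom)
  })
}

#' Synthetic test image built from planted Gabor wavelets
#'
#' Sums `n_gabors` random wavelets at ladder frequencies, with centers kept
#' away from the image border. Used to verify that the decomposition
#' recovers planted feature locations.
#'
#' @param n_gabors Number of planted wavelets (default 20).
#' @param geom An [image_geometry()].
#' @param ladder A [ladder_config()].
#' @param seed Optional integer seed.
#' @param margin_frac Fraction of the image side kept clear at each border
#'   (default 0.15).
#' @param amplitude Common amplitude of the planted wavelets.
#' @return A list with `image` (numeric matrix) and `wavelets` (the planted
#'   wavelet data.frame).
#' @export
planted_gabor_image <- function(n_gabors = 20L, geom = image_geometry(),
                                ladder = ladder_config(), seed = NULL,
                                margin_frac = 0.15, amplitude = 1) {
  with_seed(seed, {
    s <- geom$side_px
    margin <- floor(margin_frac * s)
    sfs <- ladder_sf(seq_len(ladder$n_levels), ladder)
    w <- data.frame(
      x_px = sample(margin:(s - 1L - margin), n_gabors, replace = TRUE),
      y_px = sample(margin:(s - 1L - margin), n_gabors, replace = TRUE),
      sf_cpd = sample(sfs, n_gabors, replace = TRUE),
      orientation_deg = sample(ladder_orientations(ladder), n_gabors,
                               replace = TRUE),
      phase_rad = stats::runif(n_gabors, 0, 2 * pi)
    )
    w$sigma_px <- 0.5 * geom$px_per_dva / w$sf_cpd
    w$amplitude <- amplitude
    img <- matrix(0, s, s)
    for (i in seq_len(n_gabors)) {
      win <- gabor_window(as.list(w[i, ]), geom)
      img[win$idx] <- img[win$idx] + win$vals
    }
    list(image = img, wavelets = w)
  })
}

#' Synthetic trait (AQ item) table
#'
#' A deterministic stand-in for published AQ item prevalence data: 50 items
#' in the five canonical 10-item subscales, with clinical log-diagnosticity
#' (natural log of the ASD/control endorsement prevalence ratio) planted
#' highest for social-skill items and lowest for attention-to-detail items,
#' echoing the pattern reported in the AQ validation literature. Control
#' prevalence is a constant 0.10 and the ASD prevalence is derived from the
#' planted log-ratio, so `log(prevalence_asd / prevalence_control)` is exact.
#' The same table ships as `inst/extdata/synthetic_trait_table.csv`.
#'
#' @return Data.frame with columns `item_id`, `subscale`, `prevalence_asd`,
#'   `prevalence_control`, `prevalence_ratio`, `log_diagnosticity`.
#' @export
synthetic_trait_table <- function() {
  subscales <- c("social_skill", "attention_switching", "attention_to_detail",
                 "communication", "imagination")
  ld <- c(seq(0.90, 2.04, length.out = 10),   # social skill
          seq(0.50, 1.10, length.out = 10),   # attention switching
          seq(-0.30, 0.30, length.out = 10),  # attention to detail
          seq(0.40, 1.00, length.out = 10),   # communication
          seq(0.30, 0.90, length.out = 10))   # imagination
  ctrl <- 0.10
  data.frame(
    item_id = 1:50,
    subscale = rep(subscales, each = 10),
    prevalence_asd = ctrl * exp(ld),
    prevalence_control = ctrl,
    prevalence_ratio = exp(ld),
    log_diagnosticity = ld
  )
}

#' Read a trait table CSV
#'
#' Expects columns `item_id`, `subscale` and either `prevalence_ratio` or
#' both `prevalence_asd` and `prevalence_control`; `log_diagnosticity` is
#' (re)computed with [log_diagnosticity()].
#'
#' @param path CSV path.
#' @return Validated trait table data.frame.
#' @export
read_trait_table <- function(path) {
  tt <- utils::read.csv(path)
  if (!all(c("item_id", "subscale") %in% names(tt)))
    stopf("trait table needs `item_id` and `subscale` columns")
  if (all(c("prevalence_asd", "prevalence_control") %in% names(tt))) {
    tt$log_diagnosticity <- log_diagnosticity(
      prevalence_asd = tt$prevalence_asd,
      prevalence_control = tt$prevalence_control)
  } else if ("prevalence_ratio" %in% names(tt)) {
    tt$log_diagnosticity <- log_diagnosticity(tt$prevalence_ratio)
  } else {
    stopf("trait table needs `prevalence_ratio` or both prevalence columns")
  }
  counts <- table(tt$subscale)
  if (length(counts) != 5L || any(counts != 10L))
    stopf("trait table must have 5 subscales with 10 items each")
  tt
}
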