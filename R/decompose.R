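#' Decomposition configuration
#'
#' Parameters of the iterative coarse-to-fine reduction of an image to a
#' sparse, equal-amplitude Gabor wavelet bank. At each ladder frequency the
#' per-pixel quadrature filter responses are screened to the top
#' `amplitude_quantile` fraction by amplitude, `nw` of those are sampled
#' uniformly (see [features_per_sf()]), and sampled wavelets whose
#' covariance with the iteration's input image falls below
#' `covariance_floor_ratio` times the maximum observed covariance are
#' discarded. Candidates pooled over all iterations are finally ranked by
#' covariance with the original image and the top `n_final` are kept.
#'
#' @param ladder A [ladder_config()].
#' @param amplitude_quantile Fraction of per-pixel candidates kept by the
#'   amplitude screen (default 0.25).
#' @param covariance_floor_ratio Covariance floor as a fraction of the
#'   iteration maximum (default 1/5).
#' @param n_final Final bank size (default 1000).
#' @param sigma_factor Gaussian envelope SD as a fraction of the carrier
#'   wavelength (default 0.5, about one octave of bandwidth).
#' @return An object of class `decomposition_config`.
#' @export
decomposition_config <- function(ladder = ladder_config(),
                                 amplitude_quantile = 0.25,
                                 covariance_floor_ratio = 0.2,
                                 n_final = 1000L,
                                 sigma_factor = 0.5) {
  if (amplitude_quantile <= 0 || amplitude_quantile > 1)
    stopf("`amplitude_quantile` must be in (0, 1]")
  if (covariance_floor_ratio < 0 || covariance_floor_ratio >= 1)
    stopf("`covariance_floor_ratio` must be in [0, 1)")
  assert_scalar_num(n_final, "n_final", lower = 1)
  assert_scalar_num(sigma_factor, "sigma_factor", lower = .Machine$double.eps)
  structure(
    list(ladder = ladder, amplitude_quantile = amplitude_quantile,
         covariance_floor_ratio = covariance_floor_ratio,
         n_final = as.integer(n_final), sigma_factor = sigma_factor),
    class = "decomposition_config"
  )
}

# Reflective padding indices for one axis: mirror the interior about the
# border pixel (no edge duplication), then the caller may zero-pad further.
reflect_idx <- function(s, m) {
  if (m >= s) stopf("kernel half-width (%d px) exceeds image size", m)
  c((m + 1L):2L, 1:s, (s - 1L):(s - m))
}

#' Best-fitting Gabor wavelet at every pixel
#'
#' Applies quadrature (even/odd) Gabor filter pairs at one spatial frequency
#' and all ladder orientations to the image, by FFT convolution with
#' reflective boundary padding. For each pixel it returns the orientation
#' maximizing the quadrature energy, the phase from the arctangent of the
#' quadrature pair, and the response amplitude (magnitude, approximately in
#' units of the amplitude of a locally matched wavelet). Even kernels are
#' mean-corrected, so a constant image yields zero amplitude everywhere and
#' responses are invariant to adding a constant to the image.
#'
#' @param img Numeric matrix (`side_px` x `side_px`).
#' @param sf_cpd Spatial frequency in cycles/dva; its wavelength must be at
#'   least 2 px at the given geometry.
#' @param geom An [image_geometry()].
#' @param cfg A [decomposition_config()] (for orientations and
#'   `sigma_factor`).
#' @return A list of `side_px` x `side_px` matrices: `orientation_deg`,
#'   `phase_rad`, `amplitude`.
#' @export
best_local_gabor <- function(img, sf_cpd, geom = image_geometry(),
                             cfg = decomposition_config()) {
  s <- geom$side_px
  if (!is.matrix(img) || any(dim(img) != s))
    stopf("img must be a %d x %d matrix", s, s)
  f_cpp <- sf_cpd / geom$px_per_dva
  wavelength <- 1 / f_cpp
  if (wavelength < 2)
    stopf("sf %.3g cpd is not representable: wavelength %.2f px < 2 px",
          sf_cpd, wavelength)
  sigma <- cfg$sigma_factor * wavelength
  m <- min(s - 1L, as.integer(ceiling(3.5 * sigma)))

  ri <- reflect_idx(s, m)
  P <- stats::nextn(s + 2L * m, factors = c(2, 3, 5))
  padded <- matrix(0, P, P)
  padded[seq_along(ri), seq_along(ri)] <- img[ri, ri]
  Fimg <- stats::fft(padded)

  d <- -m:m
  gx <- outer(rep(1, length(d)), d)
  gy <- outer(d, rep(1, length(d)))
  wrap <- (d %% P) + 1L
  crop <- (m + 1L):(m + s)

  best_amp <- matrix(-Inf, s, s)
  best_ori <- matrix(0, s, s)
  best_phase <- matrix(0, s, s)

  for (ori in ladder_orientations(cfg$ladder)) {
    th <- ori * pi / 180
    xr <- gx * cos(th) + gy * sin(th)
    yr <- -gx * sin(th) + gy * cos(th)
    env <- exp(-(xr^2 + yr^2) / (2 * sigma^2))
    norm <- sum(env^2) / 2 # matched-filter gain
    ke <- env * cos(2 * pi * f_cpp * xr)
    ke <- ke - mean(ke) # zero DC response
    ko <- env * sin(2 * pi * f_cpp * xr)
    K <- matrix(0, P, P)
    K[wrap, wrap] <- (ke + 1i * ko) / norm
    cc <- stats::fft(Fimg * Conj(stats::fft(K)), inverse = TRUE) / P^2
    cc <- cc[crop, crop]
    e <- Re(cc)
    o <- -Im(cc)
    amp <- sqrt(e^2 + o^2)
    upd <- amp > best_amp
    best_amp[upd] <- amp[upd]
    best_ori[upd] <- ori
    best_phase[upd] <- atan2(-o[upd], e[upd]) %% (2 * pi)
  }
  list(orientation_deg = best_ori, phase_rad = best_phase,
       amplitude = best_amp)
}

#' Sample covariance between a rendered wavelet and an image
#'
#' Both the rendered wavelet and the image are mean-centered over all
#' pixels; the sample covariance (n - 1 denominator) is the selection score
#' of the decomposition.
#'
#' @param w A one-row wavelet data.frame ([gabor_wavelet()]).
#' @param img Numeric matrix matching `geom`.
#' @param geom An [image_geometry()].
#' @return Scalar covariance.
#' @export
feature_covariance <- function(w, img, geom = image_geometry()) {
  s <- geom$side_px
  if (!is.matrix(img) || any(dim(img) != s))
    stopf("img must be a %d x %d matrix", s, s)
  n <- s * s
  win <- gabor_window(as.list(w[1, , drop = FALSE]), geom)
  (sum(win$vals * img[win$idx]) - sum(win$vals) * mean(img)) / (n - 1)
}

# Vectorized covariance of many wavelets (rows of `wavelets`) with `img`.
covariances_with <- function(wavelets, img, geom) {
  n <- geom$side_px^2
  mimg <- mean(img)
  vapply(seq_len(nrow(wavelets)), function(i) {
    win <- gabor_window(as.list(wavelets[i, ]), geom)
    (sum(win$vals * img[win$idx]) - sum(win$vals) * mimg) / (n - 1)
  }, numeric(1))
}

#' One iteration of candidate wavelet selection
#'
#' Runs the per-pixel quadrature fit at one spatial frequency, keeps the top
#' `amplitude_quantile` fraction of pixels by response amplitude, samples
#' `min(nw, available)` of them uniformly without replacement (with
#' `nw = features_per_sf(sf_cpd)`), measures each sampled wavelet's
#' covariance with the input image, and discards wavelets below the
#' covariance floor. Sampled wavelets are built with unit amplitude; the
#' quadrature response magnitude is kept in the `filter_amplitude` column.
#'
#' @param input_img The iteration's input (original image or residual).
#' @param sf_cpd The iteration's ladder frequency.
#' @param geom An [image_geometry()].
#' @param cfg A [decomposition_config()].
#' @return A list of class `candidate_set`: `sf_cpd`, `wavelets` (possibly
#'   zero-row data.frame of survivors), `covariances`, `n_candidates`
#'   (post amplitude screen), `n_sampled`.
#' @export
iteration_select <- function(input_img, sf_cpd, geom = image_geometry(),
                             cfg = decomposition_config()) {
  s <- geom$side_px
  fit <- best_local_gabor(input_img, sf_cpd, geom, cfg)
  amp <- as.vector(fit$amplitude)
  n_keep <- max(1L, ceiling(cfg$amplitude_quantile * length(amp)))
  cand <- order(amp, decreasing = TRUE)[seq_len(n_keep)]
  nw <- features_per_sf(sf_cpd, cfg$ladder)
  n_samp <- as.integer(min(nw, n_keep))
  sel <- if (n_samp == n_keep) cand else sample(cand, n_samp)

  row <- (sel - 1L) %% s      # 0-based y
  col <- (sel - 1L) %/% s     # 0-based x
  wavelength <- geom$px_per_dva / sf_cpd
  wavelets <- data.frame(
    x_px = col, y_px = row, sf_cpd = sf_cpd,
    orientation_deg = fit$orientation_deg[sel],
    phase_rad = fit$phase_rad[sel],
    sigma_px = cfg$sigma_factor * wavelength,
    amplitude = 1,
    filter_amplitude = amp[sel]
  )
  covs <- covariances_with(wavelets, input_img, geom)
  keep <- covs >= cfg$covariance_floor_ratio * max(covs)
  if (!any(keep))
    warnf("no wavelets survived the covariance floor at sf %.3g cpd", sf_cpd)
  structure(
    list(sf_cpd = sf_cpd, wavelets = wavelets[keep, , drop = FALSE],
         covariances = covs[keep], n_candidates = n_keep,
         n_sampled = n_samp),
    class = "candidate_set"
  )
}

#' Regress out selected wavelets from an image
#'
#' Least-squares fit of the image on the rendered wavelets (plus an
#' intercept), returning the residual image. The residual is orthogonal to
#' every regressor. A rank-deficient design is solved with a small ridge
#' (logged), which approximates the minimum-norm solution.
#'
#' @param prev_input Numeric matrix: the image the wavelets were selected
#'   on.
#' @param wavelets Data.frame of wavelets to use as regressors (>= 1 row).
#' @param geom An [image_geometry()].
#' @return Residual image matrix of the same size.
#' @export
residual_update <- function(prev_input, wavelets, geom = image_geometry()) {
  if (nrow(wavelets) < 1L) stopf("at least one selected wavelet is required")
  s <- geom$side_px
  n <- s * s
  k <- nrow(wavelets)
  wins <- lapply(seq_len(k), function(i)
    gabor_window(as.list(wavelets[i, ]), geom))
  nz <- vapply(wins, function(w) length(w$idx), integer(1))
  X <- Matrix::sparseMatrix(
    i = unlist(lapply(wins, `[[`, "idx")),
    j = rep(seq_len(k), nz),
    x = unlist(lapply(wins, `[[`, "vals")),
    dims = c(n, k))
  y <- as.vector(prev_input)
  ybar <- mean(y)
  xbar <- Matrix::colMeans(X)
  # center out the intercept analytically, then solve the normal equations
  xtx <- as.matrix(Matrix::crossprod(X)) - n * tcrossprod(xbar)
  xty <- as.vector(Matrix::crossprod(X, y)) - n * xbar * ybar
  beta <- tryCatch(
    solve(xtx, xty),
    error = function(e) {
      warnf("rank-deficient wavelet regressors; using ridge-regularized (near minimum-norm) solution")
      solve(xtx + diag(1e-8 * mean(diag(xtx)) + 1e-12, k), xty)
    })
  fitted <- as.vector(X %*% beta) + (ybar - sum(xbar * beta))
  matrix(y - fitted, s, s)
}

#' Decompose an image into a sparse equal-amplitude Gabor wavelet bank
#'
#' Iterates over the spatial-frequency ladder from coarse to fine. The first
#' iteration selects candidate wavelets on the original grayscale image;
#' each later iteration works on the residual of the previous input after
#' regressing out the wavelets selected in the previous iteration (see
#' [residual_update()]). All surviving candidates are pooled, ranked by
#' sample covariance with the original image, and the `n_final` wavelets
#' with the highest covariance are returned with equal (unit) amplitudes.
#' The returned bank's wavelets are ordered by decreasing covariance, so
#' the best-`k` sub-bank is simply the first `k` rows.
#'
#' @param image Numeric matrix (grayscale, any real scale).
#' @param image_id Identifier stored in the bank.
#' @param geom An [image_geometry()].
#' @param cfg A [decomposition_config()].
#' @param seed Optional integer seed; given the same seed and inputs the
#'   result is identical.
#' @param verbose Log per-iteration candidate/survivor counts.
#' @return A [feature_bank()] whose wavelet table carries a `covariance`
#'   column (score against the original image), with an attribute
#'   `decomposition` recording per-iteration counts, the config hash and the
#'   seed.
#' @export
decompose <- function(image, image_id = "image", geom = image_geometry(),
                      cfg = decomposition_config(), seed = NULL,
                      verbose = FALSE) {
  s <- geom$side_px
  if (!is.matrix(image) || any(dim(image) != s))
    stopf("image must be a %d x %d matrix", s, s)
  ladder <- cfg$ladder
  run <- function() {
    input <- image
    pooled <- vector("list", ladder$n_levels)
    counts <- data.frame(level = seq_len(ladder$n_levels), sf_cpd = NA_real_,
                         sampled = 0L, survived = 0L)
    for (k in seq_len(ladder$n_levels)) {
      sf <- ladder_sf(k, ladder)
      cs <- iteration_select(input, sf, geom, cfg)
      counts$sf_cpd[k] <- sf
      counts$sampled[k] <- cs$n_sampled
      counts$survived[k] <- nrow(cs$wavelets)
      if (verbose)
        message(sprintf("level %2d sf %.3f cpd: sampled %4d, survived %4d",
                        k, sf, cs$n_sampled, nrow(cs$wavelets)))
      if (nrow(cs$wavelets) > 0L) {
        pooled[[k]] <- cs$wavelets
        input <- residual_update(input, cs$wavelets, geom)
      }
    }
    list(pooled = do.call(rbind, pooled), counts = counts)
  }
  res <- with_seed(seed, run())
  pooled <- res$pooled
  if (is.null(pooled) || nrow(pooled) < cfg$n_final)
    stopf("decomposition pooled only %d candidate wavelets; %d required (shortfall %d)",
          if (is.null(pooled)) 0L else nrow(pooled), cfg$n_final,
          cfg$n_final - if (is.null(pooled)) 0L else nrow(pooled))
  cov_orig <- covariances_with(pooled, image, geom)
  ord <- order(cov_orig, decreasing = TRUE)[seq_len(cfg$n_final)]
  top <- pooled[ord, , drop = FALSE]
  top$amplitude <- 1
  top$covariance <- cov_orig[ord]
  top$feature_id <- seq_len(nrow(top)) - 1L
  bank <- feature_bank(image_id, top, geom)
  attr(bank, "decomposition") <- list(
    config_hash = config_hash(cfg), seed = seed, counts = res$counts)
  bank
}

#' Partial reconstruction from the best features of a bank
#'
#' Sums the first `n` wavelets of a covariance-ordered bank (as produced by
#' [decompose()]) and rescales to the 0-255 display range.
#'
#' @param bank A [feature_bank()].
#' @param n Number of leading features to use (default: all).
#' @return Integer matrix in 0..255.
#' @export
reconstruct_image <- function(bank, n = bank$n_features) {
  if (n < 1 || n > bank$n_features) stopf("`n` must be in 1..%d", bank$n_features)
  rescale_to_display(sum_features(bank, bank$wavelets$feature_id[seq_len(n)]))
}

#' Root-mean-square reconstruction error on the display scale
#'
#' RMS difference between the display-rescaled original image and the
#' display-rescaled partial reconstruction from the bank's best `n`
#' features.
#'
#' @inheritParams reconstruct_image
#' @param image The original image (any real scale; rescaled internally).
#' @return Scalar RMS error in display units (0-255).
#' @export
reconstruction_error <- function(bank, image, n = bank$n_features) {
  ref <- rescale_to_display(image)
  rec <- reconstruct_image(bank, n)
  sqrt(mean((as.numeric(ref) - as.numeric(rec))^2))
}
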