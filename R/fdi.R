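#' Per-feature raw statistic tensor (accuracy or reaction time)
#'
#' For every participant, image and feature, averages the trial statistic
#' (correctness, or RT for the RT variant) over the trials of that
#' participant and image whose presented subset contained the feature.
#' Correctness is `response == true_category` ("unsure" and wrong-animal
#' responses both count as not recognized); a logical/0-1 `correct` column
#' takes precedence when present. Cells whose feature was never shown to
#' that participant for that image are `NA`.
#'
#' @param trials Trial table with `participant_id`, `image_id`,
#'   `feature_ids` and `response`/`correct` (plus `rt_ms` for
#'   `stat = "rt"`).
#' @param n_features Features per image; inferred from the largest feature
#'   id when `NULL`.
#' @param stat `"accuracy"` or `"rt"`.
#' @return An object of class `fdi_raw`: `values` and `counts` arrays of
#'   dimension participants x images x features (participants and images in
#'   sorted order, see `dimnames`), and `source`.
#' @export
per_feature_accuracy <- function(trials, n_features = NULL,
                                 stat = c("accuracy", "rt")) {
  stat <- match.arg(stat)
  if (is.null(trials) || nrow(trials) == 0L) stopf("empty trial table")
  participants <- sort(unique(trials$participant_id))
  images <- sort(unique(trials$image_id))
  np <- length(participants); ni <- length(images)
  ids <- parse_feature_ids(trials$feature_ids)
  len <- lengths(ids)
  fid <- unlist(ids)
  if (is.null(n_features)) n_features <- max(fid) + 1L
  nf <- as.integer(n_features)
  if (any(fid < 0L | fid >= nf))
    stopf("feature ids out of range 0..%d", nf - 1L)

  pi_ <- match(trials$participant_id, participants)
  ii <- match(trials$image_id, images)
  cell <- (rep.int(pi_ - 1L, len) * ni + rep.int(ii - 1L, len)) * nf +
    fid + 1
  K <- np * ni * nf
  counts <- tabulate(cell, nbins = K)

  if (stat == "accuracy") {
    correct <- if ("correct" %in% names(trials)) {
      as.logical(trials$correct)
    } else {
      if (!"response" %in% names(trials))
        stopf("trials need a `correct` or `response` column")
      trials$response == trials$true_category
    }
    sums <- tabulate(cell[rep.int(correct, len)], nbins = K)
  } else {
    if (!"rt_ms" %in% names(trials)) stopf("trials need an `rt_ms` column")
    rs <- rowsum(rep.int(as.numeric(trials$rt_ms), len), cell)
    sums <- numeric(K)
    sums[as.numeric(rownames(rs))] <- rs[, 1]
  }
  vals <- sums / counts
  vals[counts == 0L] <- NA_real_

  to_arr <- function(v) # cell index: f fastest, then image, then participant
    aperm(array(v, dim = c(nf, ni, np)), c(3, 2, 1))
  values <- to_arr(vals)
  dimnames(values) <- list(participants, images, seq_len(nf) - 1L)
  structure(list(values = values, counts = to_arr(counts), source = stat),
            class = "fdi_raw")
}

#' Per-feature mean reaction-time tensor
#'
#' The reaction-time variant of [per_feature_accuracy()]: the cell statistic
#' is the mean RT over all trials containing the feature (no correctness
#' filter by default; pass `correct_only = TRUE` to restrict).
#'
#' @inheritParams per_feature_accuracy
#' @param correct_only Restrict to correct trials.
#' @return An `fdi_raw` object with `source = "rt"`.
#' @export
rt_fdi_raw <- function(trials, n_features = NULL, correct_only = FALSE) {
  if (correct_only) {
    keep <- if ("correct" %in% names(trials)) as.logical(trials$correct)
            else trials$response == trials$true_category
    trials <- trials[keep, , drop = FALSE]
  }
  per_feature_accuracy(trials, n_features, stat = "rt")
}

#' Z-score a raw tensor into the feature diagnosticity index (FDi)
#'
#' Within each (participant, image) slice, subtracts the slice mean and
#' divides by the slice sample SD (n - 1 denominator by default), removing
#' between-image recognizability and between-participant performance
#' differences. Missing cells (features never shown) are imputed as 0 after
#' standardization; a constant slice is set to all zeros with a warning.
#'
#' @param raw An `fdi_raw` object from [per_feature_accuracy()].
#' @param sd_type `"sample"` (n - 1) or `"population"` (n).
#' @return An object of class `fdi_tensor`: `values` (same dimensions,
#'   NaN-free), `source`, `n_imputed`, `n_constant_slices`.
#' @export
zscore_fdi <- function(raw, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  v <- raw$values
  dm <- dim(v)
  np <- dm[1]; ni <- dm[2]; nf <- dm[3]
  n_imputed <- 0L; n_const <- 0L
  for (p in seq_len(np)) {
    for (i in seq_len(ni)) {
      x <- v[p, i, ]
      obs <- !is.na(x)
      m <- mean(x[obs])
      s <- stats::sd(x[obs])
      if (sd_type == "population")
        s <- s * sqrt((sum(obs) - 1) / sum(obs))
      if (!is.finite(s) || s == 0) {
        n_const <- n_const + 1L
        v[p, i, ] <- 0
      } else {
        z <- (x - m) / s
        z[!obs] <- 0
        v[p, i, ] <- z
      }
      n_imputed <- n_imputed + sum(!obs)
    }
  }
  if (n_const > 0L)
    warnf("%d constant (uninformative) participant-image slice(s) set to zero", n_const)
  if (n_imputed > 0L)
    message(sprintf("imputed %d never-shown feature cell(s) as 0 (%.3g%% of cells)",
                    n_imputed, 100 * n_imputed / length(v)))
  structure(list(values = v, source = raw$source, n_imputed = n_imputed,
                 n_constant_slices = n_const),
            class = "fdi_tensor")
}

#' @export
print.fdi_tensor <- function(x, ...) {
  dm <- dim(x$values)
  cat(sprintf("<fdi_tensor> (%s) %d participants x %d images x %d features\n",
              x$source, dm[1], dm[2], dm[3]))
  invisible(x)
}

#' Compute FDi from a trial table in one step
#'
#' Convenience wrapper: [per_feature_accuracy()] (or the RT variant)
#' followed by [zscore_fdi()].
#'
#' @inheritParams per_feature_accuracy
#' @param source `"accuracy"` or `"rt"`.
#' @return An `fdi_tensor`.
#' @export
compute_fdi <- function(trials, n_features = NULL,
                        source = c("accuracy", "rt")) {
  source <- match.arg(source)
  zscore_fdi(per_feature_accuracy(trials, n_features, stat = source))
}

# Flatten an FDi tensor to participants x (images*features), image-major
# (image 1 features 0..nf-1, then image 2, ...). This is the canonical
# pooled-feature order used by binning and replicability.
flatten_fdi <- function(fdi) {
  v <- fdi$values
  dm <- dim(v)
  out <- matrix(NA_real_, dm[1], dm[2] * dm[3])
  for (p in seq_len(dm[1]))
    out[p, ] <- as.vector(t(array(v[p, , ], dim = dm[2:3])))
  rownames(out) <- dimnames(v)[[1]]
  out
}

# Standardized split-half matrices: S x L matrices A, B such that the
# Pearson correlation of split s is sum(A[s,] * B[s,]).
split_half_matrices <- function(M, n_splits) {
  np <- nrow(M); L <- ncol(M)
  A <- matrix(NA_real_, n_splits, L)
  B <- matrix(NA_real_, n_splits, L)
  for (s in seq_len(n_splits)) {
    perm <- sample.int(np)
    h1 <- perm[seq_len(ceiling(np / 2))]
    a <- colMeans(M[h1, , drop = FALSE])
    b <- colMeans(M[-h1, , drop = FALSE])
    A[s, ] <- (a - mean(a)) / (stats::sd(a) * sqrt(L - 1))
    B[s, ] <- (b - mean(b)) / (stats::sd(b) * sqrt(L - 1))
  }
  list(A = A, B = B)
}

#' Split-half replicability of FDi patterns
#'
#' Randomly partitions participants into two halves (sizes ceiling(n/2) and
#' floor(n/2)), averages FDi over participants within each half, flattens
#' the image x feature map, and computes the Pearson correlation between
#' halves; the replicability estimate is the mean correlation over
#' `n_splits` random splits.
#'
#' @param fdi An `fdi_tensor`.
#' @param n_splits Number of random splits (default 100).
#' @param seed Optional integer seed.
#' @return A list: `observed_r` (mean split correlation), `split_rs`.
#' @export
split_half_replicability <- function(fdi, n_splits = 100L, seed = NULL) {
  M <- flatten_fdi(fdi)
  if (nrow(M) < 4L) stopf("split-half replicability needs >= 4 participants")
  with_seed(seed, {
    sh <- split_half_matrices(M, n_splits)
    rs <- rowSums(sh$A * sh$B)
    list(observed_r = mean(rs), split_rs = rs)
  })
}

#' Permutation test of split-half replicability
#'
#' Recomputes the mean split-half correlation `n_perm` times with the second
#' half's flattened feature vector label-permuted (a fresh permutation per
#' null iteration, reusing the observed splits), yielding a null
#' distribution for the observed replicability. The p-value uses the
#' add-one estimator `(1 + #{null >= observed}) / (1 + n_perm)`.
#'
#' @param fdi An `fdi_tensor`.
#' @param n_splits Number of random splits (default 100).
#' @param n_perm Number of feature-label permutations (default 10000; a
#'   warning is issued below 100).
#' @param seed Optional integer seed.
#' @return An object of class `replicability_result`: `observed_r`,
#'   `p_value`, `n_splits`, `n_perm`, `null_mean`, `null_sd`,
#'   `null_q95`, `source`.
#' @export
permutation_p <- function(fdi, n_splits = 100L, n_perm = 10000L,
                          seed = NULL) {
  if (n_perm < 100L) warnf("n_perm = %d is very small; p-values are coarse", n_perm)
  M <- flatten_fdi(fdi)
  if (nrow(M) < 4L) stopf("permutation test needs >= 4 participants")
  L <- ncol(M)
  with_seed(seed, {
    sh <- split_half_matrices(M, n_splits)
    observed <- mean(rowSums(sh$A * sh$B))
    null <- vapply(seq_len(n_perm), function(j) {
      pi_ <- sample.int(L)
      sum(sh$A * sh$B[, pi_]) / n_splits
    }, numeric(1))
    structure(
      list(observed_r = observed,
           p_value = (1 + sum(null >= observed)) / (1 + n_perm),
           n_splits = n_splits, n_perm = n_perm,
           null_mean = mean(null), null_sd = stats::sd(null),
           null_q95 = unname(stats::quantile(null, 0.95)),
           source = fdi$source),
      class = "replicability_result")
  })
}

#' @export
print.replicability_result <- function(x, ...) {
  cat(sprintf("<replicability> %s FDi: mean split-half r = %.4f, p = %.4g (%d splits, %d permutations)\n",
              x$source, x$observed_r, x$p_value, x$n_splits, x$n_perm))
  invisible(x)
}

#' Reaction-time-based FDi tensor
#'
#' Identical pipeline to accuracy FDi with per-feature mean reaction time as
#' the cell statistic: [rt_fdi_raw()] followed by [zscore_fdi()].
#'
#' @inheritParams rt_fdi_raw
#' @return An `fdi_tensor` with `source = "rt"`.
#' @export
rt_fdi <- function(trials, n_features = NULL, correct_only = FALSE) {
  zscore_fdi(rt_fdi_raw(trials, n_features, correct_only))
}

#' Write an FDi tensor as a long CSV
#'
#' Columns `participant_id, image_id, feature_id, fdi`.
#'
#' @param fdi An `fdi_tensor`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_fdi <- function(fdi, path) {
  dn <- dimnames(fdi$values)
  dm <- dim(fdi$values)
  long <- data.frame(
    participant_id = rep(dn[[1]], times = dm[2] * dm[3]),
    image_id = rep(rep(dn[[2]], each = dm[1]), times = dm[3]),
    feature_id = rep(as.integer(dn[[3]]), each = dm[1] * dm[2]),
    fdi = as.vector(fdi$values))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
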