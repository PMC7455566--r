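#' Assign pooled features to equally sized ascending bins
#'
#' Stable sort of the pooled per-feature criterion values (ties broken by
#' image id then feature id), split into `n_bins` contiguous groups of equal
#' size; when the count is not divisible the remainder is spread over the
#' lowest bins. With the canonical 10 images x 1000 features and 5 bins,
#' every bin holds exactly 2000 features.
#'
#' @param values Per-feature criterion values (e.g. spatial frequency in
#'   cycles/dva or distance in dva), in the canonical pooled order (image-
#'   major, feature id ascending; see [feature_values()]).
#' @param n_bins Number of bins (default 5).
#' @param image_id,feature_id Optional tie-break keys aligned with `values`.
#' @return An object of class `bin_spec`: `bin` (1-based bin index per
#'   feature, original order), `boundaries` (per-bin value range and count),
#'   `n_bins`.
#' @export
assign_bins <- function(values, n_bins = 5L, image_id = NULL,
                        feature_id = NULL) {
  n <- length(values)
  if (n_bins > n) stopf("n_bins = %d exceeds the %d features", n_bins, n)
  if (anyNA(values)) stopf("criterion values contain NA")
  ord <- if (is.null(image_id)) {
    order(values, seq_len(n))
  } else {
    order(values, image_id, feature_id)
  }
  base <- n %/% n_bins
  sizes <- base + (seq_len(n_bins) <= n %% n_bins)
  bin_sorted <- rep.int(seq_len(n_bins), sizes)
  bin <- integer(n)
  bin[ord] <- bin_sorted
  boundaries <- data.frame(
    bin = seq_len(n_bins),
    lower = vapply(seq_len(n_bins), function(b) min(values[bin == b]), numeric(1)),
    upper = vapply(seq_len(n_bins), function(b) max(values[bin == b]), numeric(1)),
    n = sizes)
  structure(list(bin = bin, boundaries = boundaries, n_bins = n_bins),
            class = "bin_spec")
}

#' Pooled per-feature criterion values across image banks
#'
#' Returns, in the canonical pooled order used by the FDi tensor (images in
#' sorted id order, feature ids ascending within each image), one value per
#' feature: its spatial frequency, its distance to the nearest eye landmark,
#' or its distance to the image center (distances in degrees of visual
#' angle).
#'
#' @param banks Named list of [feature_bank()]s.
#' @param criterion `"sf"`, `"eye_distance"` or `"center_distance"`.
#' @param landmarks For `eye_distance`: named list, image id ->
#'   `list(eyes = list(c(x, y), ...))` in 0-based pixel coordinates (see
#'   [read_landmarks()]).
#' @return Data.frame `image_id`, `feature_id`, `value`.
#' @export
feature_values <- function(banks,
                           criterion = c("sf", "eye_distance",
                                         "center_distance"),
                           landmarks = NULL) {
  criterion <- match.arg(criterion)
  image_ids <- sort(vapply(banks, `[[`, character(1), "image_id"))
  names(banks) <- vapply(banks, `[[`, character(1), "image_id")
  if (criterion == "eye_distance") {
    missing <- setdiff(image_ids, names(landmarks))
    if (length(missing) > 0L)
      stopf("missing eye landmarks for image(s): %s",
            paste(missing, collapse = ", "))
  }
  out <- lapply(image_ids, function(id) {
    bank <- banks[[id]]
    w <- bank$wavelets[order(bank$wavelets$feature_id), ]
    ppd <- bank$geometry$px_per_dva
    value <- switch(
      criterion,
      sf = w$sf_cpd,
      center_distance = {
        c0 <- (bank$geometry$side_px - 1) / 2
        sqrt((w$x_px - c0)^2 + (w$y_px - c0)^2) / ppd
      },
      eye_distance = {
        eyes <- landmarks[[id]]$eyes
        if (length(eyes) < 1L) stopf("image '%s' has no eye points", id)
        d2 <- Reduce(pmin, lapply(eyes, function(e)
          (w$x_px - e[1])^2 + (w$y_px - e[2])^2))
        sqrt(d2) / ppd
      })
    data.frame(image_id = id, feature_id = w$feature_id, value = value)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-feature distances to landmarks
#'
#' Euclidean pixel distance from each feature's center to the nearest eye
#' point or to the image center, converted to degrees of visual angle.
#' A thin wrapper around [feature_values()].
#'
#' @inheritParams feature_values
#' @param criterion `"eye_distance"` or `"center_distance"`.
#' @return Data.frame `image_id`, `feature_id`, `value` (dva).
#' @export
feature_distances <- function(banks, landmarks = NULL,
                              criterion = c("eye_distance",
                                            "center_distance")) {
  feature_values(banks, match.arg(criterion), landmarks)
}

#' Read / write eye landmarks JSON
#'
#' Format: `{"image_id": {"eyes": [[x, y], [x, y]]}}` with 0-based pixel
#' coordinates.
#'
#' @param path JSON path.
#' @param landmarks Named list as described.
#' @return `read_landmarks` returns the named list; `write_landmarks`
#'   returns `path` invisibly.
#' @export
read_landmarks <- function(path) {
  raw <- jsonlite::read_json(path)
  lapply(raw, function(entry)
    list(eyes = lapply(entry$eyes, function(e) as.numeric(unlist(e)))))
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(landmarks, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Mean FDi per participant and bin
#'
#' Averages each participant's FDi values (all images pooled) within each
#' bin of a [assign_bins()] specification.
#'
#' @param fdi An `fdi_tensor`.
#' @param spec A `bin_spec` whose `bin` vector is in the tensor's canonical
#'   pooled feature order.
#' @return Numeric matrix participants x bins.
#' @export
participant_bin_means <- function(fdi, spec) {
  M <- flatten_fdi(fdi)
  if (length(spec$bin) != ncol(M))
    stopf("bin spec covers %d features but the tensor has %d",
          length(spec$bin), ncol(M))
  out <- vapply(seq_len(spec$n_bins), function(b)
    rowMeans(M[, spec$bin == b, drop = FALSE]), numeric(nrow(M)))
  out <- matrix(out, nrow = nrow(M),
                dimnames = list(rownames(M), paste0("bin", seq_len(spec$n_bins))))
  out
}

#' Two-way ANOVA on participant-level cell means
#'
#' Fits `value ~ A * B` on one observation per participant and A-level, with
#' Type II sums of squares for the unbalanced group factor.
#'
#' Two error terms are available. `error = "flat"` tests every effect
#' against the pooled residual of the fixed-effects model, reproducing the
#' error-df pattern of a flat two-way ANOVA on cell means: with 52
#' participants, 5 bins and 2 groups the interaction is F(4, 250); a 2 x 2
#' design on 52 participants gives F(1, 100). For z-scored FDi bin means
#' this flat test is structurally liberal: each participant's bin means sum
#' to exactly zero, so the subject main variance is exactly zero and the
#' flat residual df over-counts the subject-stratified df by a factor
#' b/(b-1), inflating F by the same factor. `error = "within"` (requires
#' `subject`) therefore tests the within-participant effects (A and A:B)
#' against the subject-by-A residual with df (n - g)(a - 1), and the group
#' main effect against the between-subject stratum — the calibrated
#' repeated-measures test used by the pipeline for inference.
#'
#' Degenerate all-equal input is reported as F = 0, p = 1.
#'
#' @param data Data.frame with the response and two factor columns.
#' @param response,factor_a,factor_b Column names (A = within-participant
#'   levels, B = group).
#' @param subject Column name of the participant identifier (needed for
#'   `error = "within"`).
#' @param error `"flat"` or `"within"` (see Details).
#' @return An object of class `anova_result`: `table` (effect, df1, df2, F,
#'   p), `cell_means`, `error`.
#' @export
two_way_anova <- function(data, response = "value", factor_a = "bin",
                          factor_b = "group", subject = NULL,
                          error = c("flat", "within")) {
  error <- match.arg(error)
  y <- data[[response]]
  A <- factor(data[[factor_a]])
  B <- factor(data[[factor_b]])
  if (any(table(A, B) == 0L)) stopf("empty cells in the %s x %s design",
                                    factor_a, factor_b)
  dfr <- data.frame(y = y, A = A, B = B)
  dfa <- nlevels(A) - 1L
  dfb <- nlevels(B) - 1L
  effects <- c(factor_a, factor_b, paste0(factor_a, ":", factor_b))
  cell_means <- tapply(y, list(A, B), mean)

  if (dfb == 0L) {
    # single-level grouping factor: reduces to a one-way ANOVA on A
    fit <- stats::aov(y ~ A, data = dfr)
    s <- summary(fit)[[1]]
    tab <- data.frame(
      effect = effects,
      df1 = c(dfa, 0L, 0L), df2 = c(s["Residuals", "Df"], NA, NA),
      F = c(if (stats::var(y) == 0) 0 else s["A", "F value"], NA, NA),
      p = c(if (stats::var(y) == 0) 1 else s["A", "Pr(>F)"], NA, NA))
    return(structure(list(table = tab, cell_means = cell_means,
                          error = error),
                     class = "anova_result"))
  }

  if (error == "within") {
    if (is.null(subject)) stopf("error = \"within\" needs a `subject` column")
    S <- factor(data[[subject]])
    n_subj <- nlevels(S)
    df_between <- n_subj - nlevels(B)
    df_within <- df_between * dfa
    dfs <- data.frame(df1 = c(dfa, dfb, dfa * dfb),
                      df2 = as.integer(c(df_within, df_between, df_within)))
  } else {
    df2 <- nrow(dfr) - (dfa + 1L) * (dfb + 1L)
    dfs <- data.frame(df1 = c(dfa, dfb, dfa * dfb), df2 = as.integer(df2))
  }

  if (stats::var(y) == 0) {
    tab <- cbind(data.frame(effect = effects), dfs, F = 0, p = 1)
    return(structure(list(table = tab, cell_means = cell_means,
                          error = error),
                     class = "anova_result"))
  }

  if (error == "flat") {
    fit <- stats::lm(y ~ A * B, data = dfr)
    a2 <- car::Anova(fit, type = 2)
    rows <- c("A", "B", "A:B")
    tab <- data.frame(effect = effects, df1 = as.integer(a2[rows, "Df"]),
                      df2 = as.integer(a2["Residuals", "Df"]),
                      F = a2[rows, "F value"], p = a2[rows, "Pr(>F)"])
  } else {
    dfr$S <- factor(data[[subject]])
    # Type II SS from the fixed-effects fit, tested against stratified errors
    a2 <- car::Anova(stats::lm(y ~ A * B, data = dfr), type = 2)
    ss <- stats::setNames(a2[c("A", "B", "A:B"), "Sum Sq"], c("A", "B", "A:B"))
    # between-subject stratum: subject means vs group
    smean <- tapply(dfr$y, dfr$S, mean)
    sgroup <- dfr$B[match(names(smean), as.character(dfr$S))]
    nlev_a <- nlevels(dfr$A)
    ss_between_res <- sum(tapply(smean, sgroup, function(v)
      sum((v - mean(v))^2))) * nlev_a
    # within stratum: residual after subject + fixed effects
    fit_full <- stats::lm(y ~ S + A + A:B, data = dfr)
    ss_within_res <- sum(stats::resid(fit_full)^2)
    ms_b <- ss_between_res / dfs$df2[2]
    ms_w <- ss_within_res / dfs$df2[1]
    Fv <- c(ss["A"] / dfs$df1[1] / ms_w,
            ss["B"] / dfs$df1[2] / ms_b,
            ss["A:B"] / dfs$df1[3] / ms_w)
    Fv[!is.finite(Fv)] <- 0
    tab <- cbind(data.frame(effect = effects), dfs, F = Fv,
                 p = stats::pf(Fv, dfs$df1, dfs$df2, lower.tail = FALSE))
  }
  rownames(tab) <- NULL
  structure(list(table = tab, cell_means = cell_means, error = error),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("<anova_result>\n")
  t <- x$table
  for (i in seq_len(nrow(t)))
    cat(sprintf("  %-18s F(%d, %d) = %.3f, p = %.4g\n",
                t$effect[i], t$df1[i], t$df2[i], t$F[i], t$p[i]))
  invisible(x)
}

#' Bin x group ANOVA on participant bin means
#'
#' Reshapes a participants x bins matrix into long form and runs
#' [two_way_anova()] with the AQ group as the second factor.
#'
#' @param bin_means Matrix from [participant_bin_means()].
#' @param groups Group label per participant ("high"/"low"), aligned with
#'   the rows of `bin_means`.
#' @param error Error term, `"flat"` or `"within"` (see [two_way_anova()]).
#' @return An `anova_result`.
#' @export
bin_group_anova <- function(bin_means, groups, error = c("flat", "within")) {
  np <- nrow(bin_means)
  long <- data.frame(
    value = as.vector(bin_means),
    bin = rep(colnames(bin_means) %||% paste0("bin", seq_len(ncol(bin_means))),
              each = np),
    group = rep(groups, times = ncol(bin_means)),
    participant = rep(rownames(bin_means) %||% seq_len(np),
                      times = ncol(bin_means)))
  two_way_anova(long, "value", "bin", "group", subject = "participant",
                error = match.arg(error))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Recognition-rate ANOVA (image category x AQ group)
#'
#' Computes each participant's recognition rate per image category and runs
#' the 2 x 2 fixed-effects ANOVA (error df 100 for 52 participants).
#'
#' @param trials Trial table with `correct` (or `response` +
#'   `true_category`).
#' @param groups Named group vector (names = participant ids).
#' @param error Error term (see [two_way_anova()]).
#' @return An `anova_result`.
#' @export
recognition_anova <- function(trials, groups, error = c("flat", "within")) {
  correct <- if ("correct" %in% names(trials)) as.logical(trials$correct)
             else trials$response == trials$true_category
  agg <- stats::aggregate(correct,
                          by = list(participant_id = trials$participant_id,
                                    category = trials$true_category),
                          FUN = mean)
  names(agg)[3] <- "value"
  agg$group <- unname(groups[agg$participant_id])
  two_way_anova(agg, "value", "category", "group",
                subject = "participant_id", error = match.arg(error))
}

#' Group contrast on the highest bin
#'
#' Two-sample t-test (pooled variance by default, df = n1 + n2 - 2) of the
#' highest-bin mean FDi between the high and low AQ groups.
#'
#' @param bin_means Matrix from [participant_bin_means()].
#' @param groups Group label per participant, aligned with the rows.
#' @param welch Use the Welch (unequal-variance) test instead.
#' @return A list: `t`, `df`, `p`, `group_means` (high, low).
#' @export
highest_bin_contrast <- function(bin_means, groups, welch = FALSE) {
  g <- factor(groups, levels = c("high", "low"))
  if (any(table(g) < 2L)) stopf("both groups need >= 2 participants")
  x <- bin_means[, ncol(bin_means)]
  if (stats::var(x) == 0) {
    return(list(t = 0, df = length(x) - 2L, p = 1,
                group_means = tapply(x, g, mean)))
  }
  tt <- stats::t.test(x[g == "high"], x[g == "low"], var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, group_means = tapply(x, g, mean))
}
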