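#' Reliance-on-detail slope
#'
#' Ordinary least-squares slope of a participant's five mean bin FDi values
#' on the ascending bin index 1..n_bins: a per-participant summary of how
#' strongly recognition relies on fine spatial detail.
#'
#' @param bin_means Numeric vector of bin means for one participant, or a
#'   participants x bins matrix (one slope per row).
#' @return Scalar slope, or a named vector of slopes.
#' @export
reliance_on_detail <- function(bin_means) {
  if (is.matrix(bin_means)) {
    x <- seq_len(ncol(bin_means))
    xc <- x - mean(x)
    if (anyNA(bin_means)) stopf("bin means contain NA")
    return(drop(bin_means %*% xc) / sum(xc^2))
  }
  if (anyNA(bin_means) || !is.numeric(bin_means))
    stopf("bin means must be finite numeric")
  x <- seq_along(bin_means)
  xc <- x - mean(x)
  sum(bin_means * xc) / sum(xc^2)
}

#' Clinical diagnosticity of a trait: log prevalence ratio
#'
#' Natural log of the ratio of trait (AQ item endorsement) prevalence in
#' clinically diagnosed ASD individuals to that in neurotypical controls.
#' A ratio of 7.7 corresponds to a log-diagnosticity of 2.04.
#'
#' @param ratio Positive prevalence ratio(s); or supply both prevalences.
#' @param prevalence_asd,prevalence_control Prevalences in (0, 1].
#' @return Log prevalence ratio(s).
#' @export
log_diagnosticity <- function(ratio = NULL, prevalence_asd = NULL,
                              prevalence_control = NULL) {
  if (is.null(ratio)) {
    if (is.null(prevalence_asd) || is.null(prevalence_control))
      stopf("supply `ratio` or both prevalences")
    if (any(prevalence_asd <= 0 | prevalence_asd > 1) ||
        any(prevalence_control <= 0 | prevalence_control > 1))
      stopf("prevalences must be in (0, 1]")
    ratio <- prevalence_asd / prevalence_control
  }
  if (any(!is.finite(ratio) | ratio <= 0))
    stopf("prevalence ratio must be positive")
  log(ratio)
}

#' Per-trait effect on reliance-on-detail
#'
#' For each of the 50 AQ items, the difference in mean reliance-on-detail
#' between participants endorsing the item and those not endorsing it.
#' Items endorsed by everyone or no one have an undefined effect and are
#' reported as `NA` with a warning.
#'
#' @param reliance Numeric vector of per-participant reliance-on-detail
#'   slopes.
#' @param items Participants x 50 binary endorsement matrix.
#' @return Data.frame `item_id`, `effect`, `n_endorsed`.
#' @export
trait_effects <- function(reliance, items) {
  if (length(reliance) != nrow(items))
    stopf("`reliance` and `items` disagree on the number of participants")
  n1 <- colSums(items)
  effect <- vapply(seq_len(ncol(items)), function(i) {
    x <- items[, i]
    if (all(x == 1L) || all(x == 0L)) return(NA_real_)
    mean(reliance[x == 1L]) - mean(reliance[x == 0L])
  }, numeric(1))
  if (anyNA(effect))
    warnf("%d item(s) with all-or-none endorsement have undefined effects",
          sum(is.na(effect)))
  data.frame(item_id = seq_len(ncol(items)), effect = effect,
             n_endorsed = n1)
}

#' Robust regression of trait effects on clinical diagnosticity
#'
#' Iteratively reweighted least squares with Tukey bisquare weights
#' (`MASS::rlm`); the t statistic is the slope over its robust standard
#' error with df = n - 2. On exactly linear, outlier-free data the fit
#' coincides with OLS (returned directly when the OLS fit is exact, where
#' the bisquare scale estimate degenerates).
#'
#' @param effects Response values (e.g. per-item reliance effects).
#' @param diagnosticity Predictor values (per-item log-diagnosticity).
#' @param max_iter Maximum IRLS iterations.
#' @return An object of class `robust_fit`: `slope`, `intercept`, `t_stat`,
#'   `df`, `p`, `method`, `n`.
#' @export
robust_regress <- function(effects, diagnosticity, max_iter = 50L) {
  ok <- is.finite(effects) & is.finite(diagnosticity)
  y <- effects[ok]; x <- diagnosticity[ok]
  n <- length(y)
  if (n < 3L) stopf("robust regression needs >= 3 complete pairs")
  ols <- stats::lm(y ~ x)
  if (max(abs(stats::resid(ols))) < 1e-10 * max(1, max(abs(y)))) {
    co <- stats::coef(ols)
    return(structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                          t_stat = Inf, df = n - 2L, p = 0,
                          method = "ols (exact fit)", n = n),
                     class = "robust_fit"))
  }
  fit <- MASS::rlm(y ~ x, psi = MASS::psi.bisquare, maxit = max_iter)
  if (!fit$converged)
    stopf("IRLS did not converge in %d iterations (scale %.3g)", max_iter,
          fit$s)
  co <- summary(fit)$coefficients
  t_stat <- co["x", "t value"]
  df <- n - 2L
  structure(list(slope = co["x", "Value"], intercept = co["(Intercept)", "Value"],
                 t_stat = t_stat, df = df,
                 p = 2 * stats::pt(-abs(t_stat), df),
                 method = "IRLS bisquare", n = n),
            class = "robust_fit")
}

#' @export
print.robust_fit <- function(x, ...) {
  cat(sprintf("<robust_fit> slope = %.4g, t(%d) = %.3f, p = %.4g [%s]\n",
              x$slope, x$df, x$t_stat, x$p, x$method))
  invisible(x)
}

#' Trait-type ANOVA with Bonferroni post-hoc contrasts
#'
#' One-way fixed-effects ANOVA of the 50 per-item effects across the five
#' 10-item subscales (df 4, 45), followed by one pooled-variance t-test per
#' subscale of its 10 items against the other 40 (df 48), Bonferroni
#' corrected (p x 5, capped at 1).
#'
#' @param effects 50 per-item effect values.
#' @param subscales Subscale label per item (5 labels x 10 items).
#' @return A list: `F`, `df1`, `df2`, `p`, `contrasts` (data.frame with
#'   `subscale`, `t`, `df`, `p`, `p_bonferroni`).
#' @export
subscale_anova <- function(effects, subscales) {
  g <- factor(subscales)
  counts <- table(g)
  if (length(counts) != 5L || any(counts != counts[1]))
    stopf("subscales must partition the items into 5 equal groups")
  if (anyNA(effects)) stopf("effects contain NA")
  n <- length(effects)
  df1 <- nlevels(g) - 1L
  df2 <- n - nlevels(g)
  if (stats::var(effects) == 0) {
    Fv <- 0; p <- 1
  } else {
    fit <- stats::aov(effects ~ g)
    s <- summary(fit)[[1]]
    Fv <- s["g", "F value"]
    p <- s["g", "Pr(>F)"]
  }
  contrasts <- do.call(rbind, lapply(levels(g), function(lv) {
    a <- effects[g == lv]; b <- effects[g != lv]
    if (stats::var(effects) == 0) {
      t <- 0; praw <- 1
    } else {
      tt <- stats::t.test(a, b, var.equal = TRUE)
      t <- unname(tt$statistic); praw <- tt$p.value
    }
    data.frame(subscale = lv, t = t, df = n - 2L, p = praw,
               p_bonferroni = min(1, praw * nlevels(g)))
  }))
  list(F = unname(Fv), df1 = df1, df2 = df2, p = unname(p),
       contrasts = contrasts)
}
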