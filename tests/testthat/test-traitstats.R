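test_that("reliance-on-detail is the OLS slope over bin indices", {
  expect_equal(reliance_on_detail(c(0.01, 0.02, 0.03, 0.04, 0.05)), 0.01)
  expect_equal(reliance_on_detail(rep(0.3, 5)), 0)
  v <- c(0.2, -0.1, 0.4, 0, 0.3)
  expect_equal(reliance_on_detail(v + 5), reliance_on_detail(v))
  m <- rbind(v, 2 * v)
  expect_equal(unname(reliance_on_detail(m)),
               c(reliance_on_detail(v), 2 * reliance_on_detail(v)))
  expect_equal(reliance_on_detail(v),
               unname(stats::coef(stats::lm(v ~ x, data.frame(x = 1:5)))[2]))
  expect_error(reliance_on_detail(c(1, NA, 3, 4, 5)))
})

test_that("clinical diagnosticity is the natural log prevalence ratio", {
  expect_equal(round(log_diagnosticity(7.7), 2), 2.04)
  expect_equal(log_diagnosticity(1), 0)
  expect_equal(log_diagnosticity(prevalence_asd = 0.5,
                                 prevalence_control = 0.25), log(2))
  # antisymmetry
  expect_equal(log_diagnosticity(3 / 4), -log_diagnosticity(4 / 3))
  expect_error(log_diagnosticity(0), "positive")
  expect_error(log_diagnosticity(prevalence_asd = 1.2,
                                 prevalence_control = 0.5), "\\(0, 1\\]")
})

test_that("trait effects are endorser minus non-endorser means", {
  items <- cbind(c(1, 1, 0, 0), c(1, 0, 1, 0), c(1, 1, 1, 1))
  rel <- c(0.02, 0.04, 0.01, 0.01)
  expect_warning(eff <- trait_effects(rel, items), "all-or-none")
  expect_equal(eff$effect[1], 0.02) # {0.02, 0.04} vs {0.01, 0.01}
  expect_equal(eff$effect[2], mean(c(0.02, 0.01)) - mean(c(0.04, 0.01)))
  expect_true(is.na(eff$effect[3]))
  # equal endorser/non-endorser means give a zero effect
  eff0 <- trait_effects(c(1, 2, 1, 2), cbind(c(1, 1, 0, 0)))
  expect_equal(eff0$effect, 0)
})

test_that("robust regression equals OLS on clean data and resists outliers", {
  x <- seq(0, 2, length.out = 50)
  y <- 0.001 + 0.003 * x
  fit <- robust_regress(y, x)
  expect_equal(fit$slope, 0.003, tolerance = 1e-8)
  expect_identical(fit$df, 48L)
  # noisy but clean: matches OLS closely
  set.seed(3)
  yn <- y + rnorm(50, 0, 1e-4)
  f1 <- robust_regress(yn, x)
  ols <- stats::lm(yn ~ x)
  expect_equal(f1$slope, unname(stats::coef(ols)[2]), tolerance = 0.01)
  # one gross outlier: robust slope stays closer to the truth than OLS
  yo <- yn; yo[50] <- yo[50] + 0.1
  f2 <- robust_regress(yo, x)
  ols2 <- unname(stats::coef(stats::lm(yo ~ x))[2])
  expect_lt(abs(f2$slope - 0.003), abs(ols2 - 0.003))
  expect_error(robust_regress(c(1, 2), c(1, 2)), ">= 3")
})

test_that("robust regression is calibrated under the null", {
  set.seed(11)
  big_t <- vapply(1:100, function(i) {
    x <- rnorm(50)
    y <- rnorm(50)
    abs(robust_regress(y, x)$t_stat)
  }, numeric(1))
  expect_gte(mean(big_t < 2), 0.9)
})

test_that("subscale ANOVA has df (4, 45), Bonferroni contrasts df 48", {
  tt <- synthetic_trait_table()
  set.seed(13)
  eff <- rnorm(50, 0, 0.002)
  res <- subscale_anova(eff, tt$subscale)
  expect_identical(res$df1, 4L)
  expect_identical(res$df2, 45L)
  expect_true(all(res$contrasts$df == 48L))
  expect_true(all(res$contrasts$p_bonferroni >= res$contrasts$p))
  expect_true(all(res$contrasts$p_bonferroni <= 1))
  # degenerate equal effects
  res0 <- subscale_anova(rep(0.01, 50), tt$subscale)
  expect_identical(res0$F, 0)
  expect_identical(res0$p, 1)
  expect_error(subscale_anova(eff, rep(c("a", "b"), c(30, 20))), "5 equal")
  expect_error(subscale_anova(c(NA, eff[-1]), tt$subscale), "NA")
})

test_that("a planted social-skill elevation survives Bonferroni correction", {
  tt <- synthetic_trait_table()
  hits <- withr::with_seed(17, vapply(1:20, function(i) {
    eff <- rnorm(50, 0, 0.002) + 0.003 * (tt$subscale == "social_skill")
    res <- subscale_anova(eff, tt$subscale)
    res$contrasts$p_bonferroni[res$contrasts$subscale == "social_skill"] < 0.05
  }, logical(1)))
  expect_gte(mean(hits), 0.8)
})

test_that("the bundled synthetic trait table is internally consistent", {
  tt <- synthetic_trait_table()
  expect_identical(nrow(tt), 50L)
  expect_true(all(table(tt$subscale) == 10))
  expect_equal(tt$log_diagnosticity,
               log(tt$prevalence_asd / tt$prevalence_control),
               tolerance = 1e-12)
  expect_true(all(tt$prevalence_asd <= 1 & tt$prevalence_asd > 0))
  # shipped copy matches the generator
  path <- system.file("extdata", "synthetic_trait_table.csv",
                      package = "fdimap")
  expect_true(nzchar(path))
  shipped <- read_trait_table(path)
  expect_equal(shipped$log_diagnosticity, tt$log_diagnosticity,
               tolerance = 1e-10)
  expect_identical(shipped$subscale, tt$subscale)
})
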