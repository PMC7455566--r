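test_that("bins partition pooled features into equal ascending groups", {
  vals <- withr::with_seed(2, runif(10000))
  spec <- assign_bins(vals, 5)
  expect_true(all(table(spec$bin) == 2000))
  expect_true(all(diff(spec$boundaries$lower) > 0))
  expect_true(all(spec$boundaries$lower <= spec$boundaries$upper))
  # sorted input: bin index is floor(rank / 2000)
  sorted <- sort(vals)
  spec_s <- assign_bins(sorted, 5)
  expect_identical(spec_s$bin, as.integer((seq_along(sorted) - 1) %/% 2000) + 1L)
  # ties broken deterministically, sizes preserved
  ties <- rep(1, 100)
  s1 <- assign_bins(ties, 5, image_id = rep(1:2, 50), feature_id = 1:100)
  s2 <- assign_bins(ties, 5, image_id = rep(1:2, 50), feature_id = 1:100)
  expect_identical(s1$bin, s2$bin)
  expect_true(all(table(s1$bin) == 20))
  # remainder spreads to the lowest bins
  s3 <- assign_bins(1:12, 5)
  expect_identical(unname(as.integer(table(s3$bin))), c(3L, 3L, 2L, 2L, 2L))
  expect_error(assign_bins(1:3, 5), "exceeds")
})

test_that("feature distances follow image geometry", {
  geom <- image_geometry() # 250 px / 22.5 dva
  w <- rbind(
    gabor_wavelet(60, 100, 1, 0, geom = geom),  # at the left eye
    gabor_wavelet(0, 0, 1, 0, geom = geom),     # image corner
    gabor_wavelet(124.5, 124.5, 1, 0, geom = geom)) # exact center
  bank <- feature_bank("cat01", w, geom)
  lm <- list(cat01 = list(eyes = list(c(60, 100), c(180, 100))))
  eye <- feature_distances(list(bank), lm, "eye_distance")
  expect_equal(eye$value[1], 0)
  ctr <- feature_distances(list(bank), criterion = "center_distance")
  expect_equal(ctr$value[3], 0)
  expect_equal(ctr$value[2], sqrt(2) * 124.5 / geom$px_per_dva,
               tolerance = 1e-12)
  # reflection symmetry: mirroring x of features and landmarks preserves d
  w_m <- w; w_m$x_px <- (geom$side_px - 1) - w_m$x_px
  bank_m <- feature_bank("cat01", w_m, geom)
  lm_m <- list(cat01 = list(eyes = lapply(lm$cat01$eyes, function(e)
    c((geom$side_px - 1) - e[1], e[2]))))
  eye_m <- feature_distances(list(bank_m), lm_m, "eye_distance")
  expect_equal(eye_m$value, eye$value, tolerance = 1e-12)
  expect_error(feature_distances(list(bank), list(), "eye_distance"),
               "missing eye landmarks")
})

test_that("landmarks JSON round-trips", {
  lm <- list(cat01 = list(eyes = list(c(60, 100), c(180, 100))),
             dog02 = list(eyes = list(c(90, 110))))
  path <- tempfile(fileext = ".json")
  write_landmarks(lm, path)
  expect_equal(read_landmarks(path), lm)
})

test_that("participant bin means match hand computation and center at zero", {
  # toy: 1 participant, 1 image, 4 features in 2 bins
  vals <- array(c(1, 2, 3, 6), dim = c(1, 1, 4),
                dimnames = list("p1", "a", 0:3))
  fdi <- structure(list(values = vals, source = "accuracy"),
                   class = "fdi_tensor")
  spec <- assign_bins(c(0.2, 0.4, 0.6, 0.8), 2)
  bm <- participant_bin_means(fdi, spec)
  expect_equal(unname(bm[1, ]), c((1 + 2) / 2, (3 + 6) / 2))
  # z-scored slices + equal bins => per-participant bin means average to 0
  sim <- quick_sim(n_participants = 5, n_features = 100, seed = 29)
  f <- suppressMessages(compute_fdi(sim$trials, 100))
  fv <- feature_values(make_banks(2, 100, seed = 29), "sf")
  sp <- assign_bins(fv$value, 5, fv$image_id, fv$feature_id)
  bm2 <- participant_bin_means(f, sp)
  expect_lt(max(abs(rowMeans(bm2))), 1e-9)
  # zero FDi -> zero bin means
  z <- f; z$values[] <- 0
  expect_true(all(participant_bin_means(z, sp) == 0))
})

test_that("two-way ANOVA reproduces the printed df patterns", {
  set.seed(41)
  bm <- matrix(rnorm(52 * 5), 52, dimnames = list(sprintf("p%02d", 1:52)))
  groups <- rep(c("high", "low"), c(25, 27))
  an <- bin_group_anova(bm, groups) # flat, printed-df model
  expect_identical(an$table$df1, c(4L, 1L, 4L))
  expect_true(all(an$table$df2 == 250L))
  anw <- bin_group_anova(bm, groups, error = "within")
  expect_identical(anw$table$df2, c(200L, 50L, 200L))
  # 2 x 2 on 52 participants: error df 100
  d22 <- data.frame(value = rnorm(104),
                    category = rep(c("cat", "dog"), each = 52),
                    group = rep(groups, 2),
                    participant = rep(sprintf("p%02d", 1:52), 2))
  a22 <- two_way_anova(d22, "value", "category", "group")
  expect_true(all(a22$table$df2 == 100L))
})

test_that("flat two-way F values match an explicit sums-of-squares oracle", {
  # balanced design so all SS types coincide and hand formulas apply
  set.seed(43)
  n_per <- 6; a <- 3
  g <- rep(c("g1", "g2"), each = n_per)
  subj <- paste0("s", seq_len(2 * n_per))
  long <- expand.grid(participant = subj, bin = paste0("b", 1:a),
                      stringsAsFactors = FALSE)
  long$group <- g[match(long$participant, subj)]
  long$value <- rnorm(nrow(long)) +
    0.8 * (long$bin == "b3") * (long$group == "g1")
  an <- two_way_anova(long, "value", "bin", "group")
  y <- long$value
  gm <- mean(y)
  ss_a <- sum(tapply(y, long$bin, function(v) length(v) * (mean(v) - gm)^2))
  ss_b <- sum(tapply(y, long$group, function(v) length(v) * (mean(v) - gm)^2))
  cellm <- tapply(y, list(long$bin, long$group), mean)
  ss_cells <- n_per * sum((cellm - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_err <- sum((y - cellm[cbind(long$bin, long$group)])^2)
  df2 <- nrow(long) - 2 * a
  expect_equal(an$table$F, c(ss_a / (a - 1), ss_b / 1, ss_ab / (a - 1)) /
                 (ss_err / df2), tolerance = 1e-10)
  expect_identical(an$table$df2[1], as.integer(df2))
})

test_that("a single-level group factor degenerates to a one-way ANOVA", {
  set.seed(47)
  d <- data.frame(value = rnorm(40), bin = rep(paste0("b", 1:4), 10),
                  group = "all")
  an <- two_way_anova(d, "value", "bin", "group")
  ref <- summary(stats::aov(value ~ bin, data = d))[[1]]
  expect_equal(an$table$F[1], ref["bin", "F value"], tolerance = 1e-12)
  expect_equal(an$table$p[1], ref["bin", "Pr(>F)"], tolerance = 1e-12)
  expect_true(all(is.na(an$table$F[2:3])))
  # all-equal input reports F = 0
  d0 <- d; d0$value <- 1; d0$group <- rep(c("x", "y"), each = 20)
  a0 <- two_way_anova(d0, "value", "bin", "group")
  expect_true(all(a0$table$F == 0) && all(a0$table$p == 1))
})

test_that("the highest-bin contrast reproduces df and detects planted shifts", {
  set.seed(51)
  bm <- matrix(rnorm(52 * 5), 52)
  groups <- rep(c("high", "low"), c(25, 27))
  ct <- highest_bin_contrast(bm, groups)
  expect_identical(as.integer(ct$df), 50L)
  # identical groups: t = 0, p = 1
  bm0 <- matrix(1, 10, 5)
  ct0 <- highest_bin_contrast(bm0, rep(c("high", "low"), 5))
  expect_identical(ct0$t, 0)
  expect_identical(ct0$p, 1)
  expect_error(highest_bin_contrast(bm, rep(c("high", "low"), c(1, 51))),
               ">= 2")
  # power: a 1-SD planted shift at n = 26/26 is detected almost always
  rej <- withr::with_seed(8, vapply(1:100, function(i) {
    x <- matrix(rnorm(52 * 5), 52)
    x[1:26, 5] <- x[1:26, 5] + 1
    highest_bin_contrast(x, rep(c("high", "low"), each = 26))$p < 0.05
  }, logical(1)))
  expect_gt(mean(rej), 0.9)
})
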