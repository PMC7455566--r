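test_that("per-feature accuracies match the hand-enumerated oracle", {
  raw <- per_feature_accuracy(toy_trials(), n_features = 4)
  expect_equal(dim(raw$values), c(1, 1, 4))
  expect_equal(as.vector(raw$values[1, 1, ]), c(2 / 3, 1, 1, 0))
  expect_equal(as.vector(raw$counts[1, 1, ]), c(3, 1, 1, 1))
  # z-scored oracle: mean 2/3, sample sd sqrt(2/9)
  fdi <- zscore_fdi(raw)
  expect_equal(as.vector(fdi$values[1, 1, ]),
               c(0, 0.7071068, 0.7071068, -1.4142136), tolerance = 1e-6)
  expect_error(per_feature_accuracy(toy_trials()[0, ]), "empty")
})

test_that("never-shown features are missing, then imputed at zero", {
  tr <- toy_trials() # feature 4 never shown
  raw <- per_feature_accuracy(tr, n_features = 5)
  expect_true(is.na(raw$values[1, 1, 5]))
  expect_message(fdi <- zscore_fdi(raw), "imputed 1")
  expect_identical(fdi$values[1, 1, 5], 0)
  expect_identical(fdi$n_imputed, 1L)
})

test_that("FDi is invariant to affine transforms of raw accuracy", {
  sim <- quick_sim(n_participants = 5, n_features = 80, seed = 13)
  raw <- per_feature_accuracy(sim$trials, 80)
  f1 <- suppressMessages(zscore_fdi(raw))
  shifted <- raw
  shifted$values[2, , ] <- 0.2 + 3 * shifted$values[2, , ] # one participant
  f2 <- suppressMessages(zscore_fdi(shifted))
  expect_equal(f1$values, f2$values, tolerance = 1e-9)
})

test_that("z-scored slices have mean 0 and sd 1; constant slices warn", {
  sim <- quick_sim(n_participants = 6, n_features = 60, seed = 17)
  fdi <- suppressMessages(compute_fdi(sim$trials, 60))
  for (p in 1:6) {
    for (i in 1:2) {
      expect_lt(abs(mean(fdi$values[p, i, ])), 1e-9)
      expect_lt(abs(stats::sd(fdi$values[p, i, ]) - 1), 0.15) # few imputed 0s
    }
  }
  # fully observed toy slice: sd exactly 1
  f <- zscore_fdi(per_feature_accuracy(toy_trials(), 4))
  expect_lt(abs(stats::sd(f$values[1, 1, ]) - 1), 1e-9)
  # an all-correct participant-image is uninformative
  tr <- toy_trials(); tr$response <- "cat"
  expect_warning(fc <- zscore_fdi(per_feature_accuracy(tr, 4)), "constant")
  expect_true(all(fc$values == 0))
})

test_that("split-half replicability is 1 for identical participants and ~0 for noise", {
  vals <- withr::with_seed(3, array(rep(rnorm(2 * 500), each = 6),
                                    dim = c(6, 2, 500)))
  dimnames(vals) <- list(paste0("p", 1:6), c("a", "b"), 0:499)
  ident <- structure(list(values = vals, source = "accuracy"),
                     class = "fdi_tensor")
  r <- split_half_replicability(ident, n_splits = 10, seed = 1)
  expect_equal(r$observed_r, 1, tolerance = 1e-12)
  noise <- ident
  noise$values <- withr::with_seed(4, array(rnorm(6 * 2 * 500),
                                            dim = c(6, 2, 500)))
  rn <- split_half_replicability(noise, n_splits = 30, seed = 2)
  expect_lt(abs(rn$observed_r), 0.06)
  # determinism and the participant floor
  expect_identical(split_half_replicability(noise, 10, seed = 5)$observed_r,
                   split_half_replicability(noise, 10, seed = 5)$observed_r)
  small <- ident; small$values <- vals[1:3, , , drop = FALSE]
  expect_error(split_half_replicability(small), ">= 4")
})

test_that("the permutation null gives the floor p for perfect replicability", {
  vals <- withr::with_seed(8, array(rep(rnorm(1 * 800), each = 6),
                                    dim = c(6, 1, 800)))
  dimnames(vals) <- list(paste0("p", 1:6), "a", 0:799)
  ident <- structure(list(values = vals, source = "accuracy"),
                     class = "fdi_tensor")
  res <- suppressWarnings(permutation_p(ident, n_splits = 10, n_perm = 199,
                                        seed = 3))
  expect_equal(res$p_value, 1 / 200)
  expect_gt(res$p_value, 0)
  expect_lte(res$p_value, 1)
  expect_warning(permutation_p(ident, 10, n_perm = 50, seed = 1), "small")
})

test_that("RT-based FDi runs the same pipeline on reaction times", {
  sim <- quick_sim(n_participants = 5, n_features = 60, seed = 19)
  f <- suppressMessages(rt_fdi(sim$trials, 60))
  expect_identical(f$source, "rt")
  expect_lt(abs(mean(f$values[1, 1, ])), 1e-9)
  # constant RTs are uninformative
  tr <- sim$trials; tr$rt_ms <- 500
  expect_warning(fc <- suppressMessages(rt_fdi(tr, 60)), "constant")
  expect_true(all(fc$values == 0))
})

test_that("FDi long CSV export has one row per cell", {
  sim <- quick_sim(n_participants = 4, n_features = 30, seed = 23)
  fdi <- suppressMessages(compute_fdi(sim$trials, 30))
  path <- tempfile(fileext = ".csv")
  write_fdi(fdi, path)
  long <- utils::read.csv(path)
  expect_identical(nrow(long), 4L * 2L * 30L)
  i <- which(long$participant_id == "p02" & long$image_id == "cat01" &
               long$feature_id == 7)
  expect_equal(long$fdi[i], fdi$values["p02", "cat01", "7"])
})
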