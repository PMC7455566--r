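test_that("quadrature filtering recovers a planted wavelet's parameters", {
  geom <- test_geom(100)
  w <- gabor_wavelet(30, 70, sf_cpd = 1, orientation_deg = 40,
                     phase_rad = 1.2, geom = geom)
  img <- render_wavelet(w, geom)
  fit <- best_local_gabor(img, 1, geom)
  at <- which(fit$amplitude == max(fit$amplitude), arr.ind = TRUE)
  expect_equal(unname(at[1, ]), c(71, 31)) # row = y + 1, col = x + 1
  expect_equal(fit$orientation_deg[71, 31], 40)
  expect_equal(fit$phase_rad[71, 31], 1.2, tolerance = 1e-3)
  expect_equal(fit$amplitude[71, 31], 1, tolerance = 1e-3)
  expect_error(best_local_gabor(img, 60, geom), "wavelength")
})

test_that("filter amplitudes ignore the image mean", {
  geom <- test_geom(64)
  flat <- best_local_gabor(matrix(5, 64, 64), 1, geom)
  expect_lt(max(flat$amplitude), 1e-9)
  img <- render_wavelet(gabor_wavelet(32, 32, 1, 30, geom = geom), geom)
  a1 <- best_local_gabor(img, 1, geom)$amplitude
  a2 <- best_local_gabor(img + 7, 1, geom)$amplitude
  expect_equal(a1, a2, tolerance = 1e-9)
})

test_that("iteration_select respects the nw bound and covariance floor", {
  geom <- test_geom(64)
  img <- planted_gabor_image(6, geom, seed = 4)$image
  cfg <- decomposition_config()
  sf <- ladder_sf(20)
  withr::with_seed(1, cs <- iteration_select(img, sf, geom, cfg))
  expect_lte(nrow(cs$wavelets), features_per_sf(sf))
  expect_lte(cs$n_sampled, features_per_sf(sf))
  expect_true(all(cs$covariances >=
                    cfg$covariance_floor_ratio * max(cs$covariances)))
  expect_true(all(cs$wavelets$sf_cpd == sf))
  # floor 0: nothing is discarded by covariance
  cfg0 <- decomposition_config(covariance_floor_ratio = 0)
  withr::with_seed(1, cs0 <- iteration_select(img, sf, geom, cfg0))
  expect_identical(nrow(cs0$wavelets), cs0$n_sampled)
})

test_that("residual regression removes selected wavelets", {
  geom <- test_geom(64)
  w <- gabor_wavelet(30, 30, sf_cpd = 0.8, orientation_deg = 60,
                     phase_rad = 0.5, amplitude = 2, geom = geom)
  img <- render_wavelet(w, geom) + 3 # DC offset handled by the intercept
  res <- residual_update(img, w, geom)
  expect_lt(sqrt(mean(res^2)), 1e-8)
  # residual orthogonal to regressors, energy non-increasing
  bank <- synthetic_feature_bank("x", 15, geom, seed = 6)
  noise <- matrix(rnorm(64^2), 64)
  res2 <- residual_update(noise, bank$wavelets, geom)
  for (i in c(1, 7, 15)) {
    reg <- render_wavelet(bank$wavelets[i, ], geom)
    expect_lt(abs(sum(res2 * reg)) / sqrt(sum(reg^2) * sum(noise^2)), 1e-6)
  }
  expect_lte(sum(res2^2), sum(noise^2))
  expect_error(residual_update(noise, bank$wavelets[0, ], geom))
})

test_that("feature covariance has the expected sign and zero behavior", {
  geom <- test_geom(64)
  w <- gabor_wavelet(32, 32, 1, 20, phase_rad = 0.3, geom = geom)
  img <- render_wavelet(w, geom)
  cv <- feature_covariance(w, img, geom)
  expect_equal(cv, stats::var(as.vector(img)), tolerance = 1e-6)
  expect_gt(cv, 0)
  expect_equal(feature_covariance(w, matrix(2, 64, 64), geom), 0,
               tolerance = 1e-12)
  expect_equal(feature_covariance(w, -img, geom), -cv, tolerance = 1e-12)
})

test_that("decompose is seed-deterministic and covariance-ranked", {
  geom <- test_geom(64)
  pg <- planted_gabor_image(10, geom, seed = 7)
  cfg <- decomposition_config(n_final = 150)
  b1 <- suppressWarnings(decompose(pg$image, "synth", geom, cfg, seed = 11))
  b2 <- suppressWarnings(decompose(pg$image, "synth", geom, cfg, seed = 11))
  expect_identical(b1$wavelets, b2$wavelets)
  expect_identical(b1$n_features, 150L)
  expect_true(all(diff(b1$wavelets$covariance) <= 0))
  expect_true(all(b1$wavelets$amplitude == b1$wavelets$amplitude[1]))
  # selected frequencies come from the ladder
  sfs <- ladder_sf(1:29)
  expect_true(all(vapply(b1$wavelets$sf_cpd,
                         function(s) any(abs(s - sfs) < 1e-12), logical(1))))
  # a different seed gives a different (but equally sized) bank
  b3 <- suppressWarnings(decompose(pg$image, "synth", geom, cfg, seed = 12))
  expect_false(identical(b1$wavelets, b3$wavelets))
  # impossible demands fail loudly
  expect_error(suppressWarnings(
    decompose(pg$image, "synth", geom,
              decomposition_config(n_final = 50000))),
    "shortfall")
})

test_that("decompose recovers planted wavelets and improves with more features", {
  geom <- test_geom(64)
  pg <- planted_gabor_image(10, geom, seed = 21)
  bank <- suppressWarnings(
    decompose(pg$image, "synth", geom,
              decomposition_config(n_final = 400), seed = 5))
  d2 <- vapply(seq_len(nrow(pg$wavelets)), function(i)
    min((bank$wavelets$x_px - pg$wavelets$x_px[i])^2 +
          (bank$wavelets$y_px - pg$wavelets$y_px[i])^2), numeric(1))
  expect_gte(mean(d2 <= 4), 0.8) # within 2 px
  # error falls with bank size while the bank is still under-complete
  errs <- vapply(c(10, 25, 50, 100), function(n)
    reconstruction_error(bank, pg$image, n), numeric(1))
  expect_true(all(diff(errs) < 0))
})
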