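test_that("per-band feature matrices have one row per epoch, one column per channel", {
  rec <- mini_rec(fs = 128, secs = 10, seed = 16, group = "PD_OFF")
  ep <- segment(bandpass(rec, 8, 13), n_epochs = 10)
  fm <- build_band_features(ep, eeg_bands("alpha"))
  expect_equal(dim(fm$values), c(10, 8))
  expect_equal(fm$feature_names[1], "alpha_Fp1")
  expect_equal(fm$labels, rep(1L, 10))
  expect_true(all(fm$values >= 0))

  # the vectorised path agrees with epoch-at-a-time welch_psd + band_power
  direct <- band_power(welch_psd(ep$data[3, , ], ep$fs),
                       eeg_bands("alpha"))
  expect_equal(unname(fm$values[3, ]), unname(direct), tolerance = 1e-12)

  zero <- new_recording(matrix(0, 8, 128 * 5), 128, mini_channels)
  fz <- build_band_features(segment(zero, n_epochs = 5), eeg_bands("alpha"))
  expect_true(all(fz$values == 0))
})

test_that("stacking is band-major and unstacking inverts it", {
  rec <- mini_rec(fs = 128, secs = 8, seed = 17)
  per_band <- lapply(seq_len(5), function(b)
    build_band_features(segment(bandpass(rec, eeg_bands()$low_hz[b],
                                         eeg_bands()$high_hz[b]),
                                n_epochs = 8),
                        eeg_bands()[b, ]))
  names(per_band) <- eeg_bands()$name
  st <- stack_bands(per_band)
  expect_equal(ncol(st$values), 5 * 8)
  expect_equal(st$bands, eeg_bands()$name)
  expect_equal(st$feature_names[1:8], per_band$delta$feature_names)
  # list order must not matter: canonical band order wins
  st2 <- stack_bands(per_band[c("gamma", "delta", "alpha", "beta", "theta")])
  expect_identical(st$values, st2$values)

  un <- unstack_bands(st)
  for (b in names(per_band)) {
    expect_identical(un[[b]]$values, per_band[[b]]$values)
    expect_identical(un[[b]]$feature_names, per_band[[b]]$feature_names)
  }

  m <- features_to_map(st, 2)
  expect_equal(dim(m), c(5, 8))
  expect_equal(m["theta", "C3"],
               unname(st$values[2, which(st$feature_names == "theta_C3")]))

  bad <- per_band
  bad$theta <- subset_rows <- pdeeg:::subset_features(bad$theta, 1:4)
  expect_error(stack_bands(bad), "disagree")
})

test_that("single-channel stacking reshapes to a 5 x 1 map", {
  rec <- new_recording(matrix(rnorm(128 * 6), 1), 128, "Cz")
  per_band <- lapply(seq_len(5), function(b)
    build_band_features(segment(rec, n_epochs = 6), eeg_bands()[b, ]))
  names(per_band) <- eeg_bands()$name
  st <- stack_bands(per_band)
  expect_equal(ncol(st$values), 5)
  expect_equal(dim(features_to_map(st, 1)), c(5, 1))
})

test_that("the standardizer is fitted on training rows only", {
  set.seed(18)
  tr <- toy_features(matrix(rnorm(2000 * 6, mean = 3, sd = 2), 2000, 6),
                     labels = rep(0:1, 1000), standardized = FALSE)
  sc <- fit_standardizer(tr)
  z <- apply_standardizer(sc, tr)
  expect_lt(max(abs(colMeans(z$values))), 1e-10)
  expect_lt(max(abs(apply(z$values, 2, sd) - 1)), 1e-10)

  # held-out rows from the same distribution stay near zero mean
  te <- toy_features(matrix(rnorm(400 * 6, mean = 3, sd = 2), 400, 6),
                     labels = rep(0:1, 200), standardized = FALSE)
  zt <- apply_standardizer(sc, te)
  expect_lt(max(abs(colMeans(zt$values))), 3 / sqrt(400))

  # degenerate column: mapped to zero with a warning
  trc <- tr
  trc$values[, 2] <- 5
  expect_warning(scc <- fit_standardizer(trc), "zero-variance")
  zc <- suppressWarnings(apply_standardizer(scc, trc))
  expect_true(all(zc$values[, 2] == 0))

  expect_error(apply_standardizer(list(), tr), "fitted")
  other <- toy_features(matrix(rnorm(20), 10, 2), labels = rep(0:1, 5),
                        standardized = FALSE)
  expect_error(apply_standardizer(sc, other), "different feature columns")
  expect_error(fit_standardizer(pdeeg:::subset_features(tr, 1)), ">= 2")
})
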