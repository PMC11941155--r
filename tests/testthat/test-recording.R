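test_that("band table and band definitions enforce their invariants", {
  b <- eeg_bands()
  expect_equal(b$name, c("delta", "theta", "alpha", "beta", "gamma"))
  expect_equal(b$low_hz, c(1, 4, 8, 13, 30))
  expect_equal(b$high_hz, c(4, 8, 13, 30, 48))
  # non-overlapping except at shared edges
  expect_equal(b$high_hz[-5], b$low_hz[-1])
  expect_equal(eeg_bands(c("gamma", "alpha"))$name, c("gamma", "alpha"))
  expect_error(eeg_bands("mu"), "unknown band")
  expect_error(band_definition("x", 10, 5), "low_hz < high_hz")
  expect_error(band_definition("x", -1, 5), "low_hz < high_hz")
})

test_that("dataset presets carry the two published geometries", {
  p1 <- dataset_preset("dataset1")
  expect_equal(p1$n_channels, 32L)
  expect_equal(p1$fs, 512)
  expect_equal(p1$crop_s, 180)
  expect_equal(p1$n_epochs, 180L)
  expect_length(p1$channels, 32)
  p2 <- dataset_preset("dataset2")
  expect_equal(p2$n_channels, 29L)
  expect_equal(p2$fs, 500)
  expect_equal(p2$n_epochs, 120L)
  expect_length(p2$channels, 29)
  # the 29-channel montage is a subset of the 32-channel one and keeps the
  # ocular proxies
  expect_true(all(p2$channels %in% p1$channels))
  expect_true(all(c("Fp1", "Fp2") %in% p2$channels))
})

test_that("recording construction rejects invalid inputs", {
  sig <- matrix(rnorm(2 * 300), 2)
  expect_error(new_recording(sig, 128, c("Fp1", "Fp1")), "duplicate")
  expect_error(new_recording(sig, 128, c("Fp1", "fp1 ")), "duplicate")
  expect_error(new_recording(sig, 50, c("Fp1", "Fp2")), "Nyquist")
  expect_error(new_recording(sig, 128, c("Fp1", "Fp2"), group = "SICK"),
               "group")
  expect_error(new_recording(sig, 128, "Fp1"), "channel names")
  rec <- new_recording(sig, 128, c("Fp1", "Fp2"))
  expect_equal(rec$duration_s, 300 / 128)
})

test_that("validate_montage reports discrepancies and is pure", {
  cfg <- synth_config(dataset_preset("dataset2"), n_pd = 1, n_hc = 0,
                      duration_s = 1, blink_rate = 0, seed = 5)
  rec <- simulate_recording(cfg, "p1", "PD")
  p2 <- dataset_preset("dataset2")
  expect_identical(validate_montage(rec, p2), character())
  expect_identical(validate_montage(rec, p2), validate_montage(rec, p2))

  # missing Fp2 -> named in exactly one discrepancy
  drop <- which(rec$channel_names == "Fp2")
  rec_miss <- new_recording(rec$signal[-drop, ], rec$fs,
                            rec$channel_names[-drop])
  rep_miss <- validate_montage(rec_miss, p2)
  expect_true(any(grepl("Fp2", rep_miss)))

  # 29-channel recording against the 32-channel preset
  rep12 <- validate_montage(rec, dataset_preset("dataset1"))
  expect_true(any(grepl("29", rep12) & grepl("32", rep12)))

  # matching is case-insensitive and ignores reference suffixes
  rec_alias <- new_recording(rec$signal, rec$fs,
                             paste0(toupper(rec$channel_names), "-REF"))
  expect_identical(validate_montage(rec_alias, p2), character())
})
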