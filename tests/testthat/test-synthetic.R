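test_that("an alpha-only configuration concentrates power in 8-13 Hz", {
  cfg <- synth_config(dataset_preset("dataset2"), n_pd = 0, n_hc = 1,
                      duration_s = 4, seed = 21,
                      band_amplitudes = c(delta = 0, theta = 0, alpha = 5,
                                          beta = 0, gamma = 0),
                      pink_noise_amp = 0, white_noise_amp = 0,
                      blink_rate = 0)
  rec <- simulate_recording(cfg, "s1", "HC")
  # 0.5 Hz grid so window leakage at the band edges stays negligible
  sp <- welch_psd(rec$signal[1, , drop = FALSE], rec$fs,
                  window_len = 2 * rec$fs)
  total <- sum(sp$power[sp$freqs >= 1 & sp$freqs < 48])
  alpha <- sum(sp$power[sp$freqs >= 8 & sp$freqs < 13])
  expect_gt(alpha / total, 0.9)
})

test_that("simulation is deterministic per seed and decorrelated across seeds", {
  base <- function(seed, secs = 2)
    synth_config(dataset_preset("dataset2"), n_pd = 1, n_hc = 0,
                 duration_s = secs, seed = seed, blink_rate = 0)
  a <- simulate_recording(base(7), "p1", "PD")
  b <- simulate_recording(base(7), "p1", "PD")
  expect_identical(a$signal, b$signal)
  expect_false(identical(a$signal, simulate_recording(base(8), "p1",
                                                      "PD")$signal))
  # narrowband oscillations decorrelate slowly, so judge |r| over a window
  # long enough for a few hundred effective samples
  a30 <- simulate_recording(base(7, 30), "p1", "PD")
  c30 <- simulate_recording(base(8, 30), "p1", "PD")
  expect_lt(abs(cor(a30$signal[1, ], c30$signal[1, ])), 0.1)
  expect_error(simulate_recording(base(7), "p1", "XX"), "group")
})

test_that("the planted theta effect separates groups in mean band power", {
  cfg <- synth_config(dataset_preset("dataset2"), n_pd = 12, n_hc = 12,
                      duration_s = 5, seed = 31,
                      pd_band_multipliers = c(delta = 1, theta = 2,
                                              alpha = 1, beta = 1,
                                              gamma = 1),
                      subject_sd = 0.1, blink_rate = 0)
  recs <- simulate_cohort(cfg)
  theta <- eeg_bands("theta")
  # per-subject mean theta power over channels from the raw Welch spectrum
  pow <- vapply(recs, function(r) {
    sp <- welch_psd(r$signal, r$fs, window_len = r$fs)
    mean(band_power(sp, theta))
  }, 0)
  grp <- vapply(recs, `[[`, "", "group")
  tt <- t.test(pow[grp == "PD"], pow[grp == "HC"], alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("band-power ratios converge to the squared multipliers", {
  cfg <- synth_config(dataset_preset("dataset2"), n_pd = 50, n_hc = 50,
                      duration_s = 8, seed = 99,
                      pd_band_multipliers = c(delta = 1, theta = 2,
                                              alpha = 1, beta = 0.4,
                                              gamma = 0.4),
                      subject_sd = 0.1, pink_noise_amp = 0,
                      white_noise_amp = 0, blink_rate = 0)
  pb <- cohort_band_features(simulate_cohort(cfg), ica = FALSE)
  for (b in c("theta", "gamma", "alpha")) {
    v <- rowMeans(pb[[b]]$values)
    ratio <- mean(v[pb[[b]]$labels == 1]) / mean(v[pb[[b]]$labels == 0])
    target <- cfg$pd_band_multipliers[[b]]^2
    expect_lt(abs(ratio - target) / target, 0.1)
  }
})

test_that("blink injection follows its Poisson and spatial contracts", {
  quiet <- new_recording(matrix(0, 8, 128 * 180), 128, mini_channels)
  expect_identical(inject_blinks(quiet, rate = 0, amp = 50)$signal,
                   quiet$signal)
  counts <- vapply(1:20, function(s)
    inject_blinks(quiet, rate = 12, amp = 50, seed = s)$n_blinks, 0L)
  # mean of 20 Poisson(36) draws within 3 standard errors
  expect_lt(abs(mean(counts) - 36), 3 * sqrt(36 / 20))

  homog <- mini_rec(fs = 128, secs = 30, seed = 6)
  blk <- inject_blinks(homog, rate = 20, amp = 60, seed = 3)
  rms <- function(x) sqrt(mean(x^2))
  expect_gt(rms(blk$signal["Fp1", ]), rms(blk$signal["Oz", ]))

  no_fp <- new_recording(matrix(0, 2, 256), 128, c("C3", "C4"))
  expect_error(inject_blinks(no_fp, 10, 50), "Fp1/Fp2")
})

test_that("cohorts have the published composition", {
  c1 <- synth_config(dataset_preset("dataset1"), duration_s = 2,
                     blink_rate = 0, seed = 1)
  recs1 <- simulate_cohort(c1)
  expect_length(recs1, 46)                    # 16 HC + 2 x 15 PD sessions
  grp <- vapply(recs1, `[[`, "", "group")
  expect_equal(sum(grp == "HC"), 16)
  expect_equal(sum(grp == "PD_OFF"), 15)
  expect_equal(sum(grp == "PD_ON"), 15)
  # both sessions of a patient share the subject id
  sid <- vapply(recs1, `[[`, "", "subject_id")
  expect_equal(sort(sid[grp == "PD_OFF"]), sort(sid[grp == "PD_ON"]))

  c2 <- synth_config(dataset_preset("dataset2"), duration_s = 2,
                     blink_rate = 0, seed = 1)
  recs2 <- simulate_cohort(c2)
  expect_length(recs2, 28)
  expect_equal(sum(vapply(recs2, `[[`, "", "group") == "PD"), 14)

  solo <- simulate_cohort(synth_config(dataset_preset("dataset2"), n_pd = 1,
                                       n_hc = 0, duration_s = 2,
                                       blink_rate = 0))
  expect_length(solo, 1)
  expect_equal(solo[[1]]$group, "PD")

  # medicated sessions sit between unmedicated and control spectra: the ON
  # multiplier is the OFF one pulled halfway to 1
  expect_equal(pdeeg:::group_multipliers(c1, "PD_ON"),
               1 + (pdeeg:::group_multipliers(c1, "PD_OFF") - 1) / 2)
})
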