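# Synthetic resting-state EEG cohorts with planted spectral group effects.
#
# Each channel is a sum of five band-limited Gaussian noise oscillations
# (unit RMS, scaled by per-band amplitudes), 1/f "pink" background noise,
# broadband white noise, and optional stereotyped eye blinks concentrated
# on the frontopolar channels. Patients differ from controls through
# multiplicative per-band amplitude effects (elevated theta, depressed beta
# and gamma by default); subjects differ through log-normal per-band random
# effects drawn once per subject.

#' Configuration for a synthetic EEG cohort
#'
#' Defaults describe a plausible resting-state cohort: oscillation
#' amplitudes of a few microvolts with alpha dominant, a patient effect in
#' the direction reported for Parkinson's disease (theta up, beta and gamma
#' down), moderate between-subject variability and a typical spontaneous
#' blink rate.
#'
#' @param preset a [dataset_preset()] list (geometry, duration, montage).
#' @param n_pd,n_hc subjects per group; preset defaults are 15/16 for
#'   `dataset1` and 14/14 for `dataset2`.
#' @param band_amplitudes named per-band baseline oscillation RMS amplitudes
#'   (uV).
#' @param pd_band_multipliers named per-band multiplicative patient effects
#'   (dimensionless, > 0).
#' @param subject_sd log-scale SD of the per-subject, per-band amplitude
#'   random effect.
#' @param pink_noise_amp,white_noise_amp RMS amplitudes (uV) of the 1/f
#'   background (shaped over 0.5--50 Hz) and of broadband white noise.
#' @param blink_rate spontaneous blink rate (events/min).
#' @param blink_amp blink peak amplitude on Fp1/Fp2 (uV).
#' @param duration_s recording duration; defaults to the preset crop length.
#'   Shorten for quick tests; the stated cohort uses the preset value.
#' @param seed integer master seed; every subject draws from a deterministic
#'   substream keyed by the seed, the subject id and the group, so cohorts
#'   are extensible without reshuffling existing subjects.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(preset = dataset_preset("dataset1"),
                         n_pd = NULL, n_hc = NULL,
                         band_amplitudes = c(delta = 6, theta = 5, alpha = 10,
                                             beta = 3, gamma = 1.5),
                         pd_band_multipliers = c(delta = 1, theta = 1.5,
                                                 alpha = 1, beta = 0.7,
                                                 gamma = 0.7),
                         subject_sd = 0.2,
                         pink_noise_amp = 4, white_noise_amp = 1,
                         blink_rate = 12, blink_amp = 80,
                         duration_s = NULL, seed = 42) {
  n_pd <- n_pd %||% if (preset$name == "dataset1") 15L else 14L
  n_hc <- n_hc %||% if (preset$name == "dataset1") 16L else 14L
  bands <- eeg_bands()$name
  band_amplitudes <- band_amplitudes[bands]
  pd_band_multipliers <- pd_band_multipliers[bands]
  if (anyNA(band_amplitudes) || any(band_amplitudes < 0))
    stopf("band_amplitudes must name all five bands with values >= 0")
  if (anyNA(pd_band_multipliers) || any(pd_band_multipliers <= 0))
    stopf("pd_band_multipliers must name all five bands with values > 0")
  amps <- c(pink_noise_amp, white_noise_amp, blink_amp, subject_sd)
  if (any(amps < 0) || blink_rate < 0)
    stopf("amplitudes, subject_sd and blink_rate must be >= 0")
  structure(list(
    preset = preset, n_pd = as.integer(n_pd), n_hc = as.integer(n_hc),
    band_amplitudes = band_amplitudes,
    pd_band_multipliers = pd_band_multipliers,
    subject_sd = subject_sd, pink_noise_amp = pink_noise_amp,
    white_noise_amp = white_noise_amp, blink_rate = blink_rate,
    blink_amp = blink_amp,
    duration_s = duration_s %||% preset$crop_s,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# Gaussian noise confined to [low, high) Hz by Fourier masking, unit RMS.
band_limited_noise <- function(n, fs, low, high) {
  x <- rnorm(n)
  X <- fft(x)
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f <- pmin(f, fs - f)                       # fold to [0, fs/2]
  X[!(f >= low & f < high)] <- 0
  y <- Re(fft(X, inverse = TRUE)) / n
  r <- sqrt(mean(y^2))
  if (r == 0) y else y / r
}

# 1/f-power background noise shaped over [low, high) Hz, unit RMS.
pink_noise <- function(n, fs, low = 0.5, high = 50) {
  x <- rnorm(n)
  X <- fft(x)
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f <- pmin(f, fs - f)
  shape <- ifelse(f >= low & f < high, 1 / sqrt(pmax(f, low)), 0)
  y <- Re(fft(X * shape, inverse = TRUE)) / n
  y / sqrt(mean(y^2))
}

# Effective per-band multipliers for a group. Medicated patients (PD_ON)
# have their multipliers pulled halfway back toward 1.
group_multipliers <- function(cfg, group) {
  m <- cfg$pd_band_multipliers
  switch(group,
    HC = rep(1, length(m)),
    PD_ON = 1 + (m - 1) / 2,
    PD_OFF = m,
    PD = m,
    stopf("unknown group '%s'", group))
}

#' Simulate one synthetic EEG recording
#'
#' Per channel the signal is the sum over bands of `a_b * s_b(t)` --- where
#' `s_b` is unit-RMS band-limited Gaussian noise and `a_b` combines the
#' baseline band amplitude, the subject's log-normal random effect and the
#' group multiplier --- plus 1/f and white background noise. Blinks are
#' injected afterwards when `cfg$blink_rate > 0`. Fully deterministic given
#' `(cfg$seed, subject_id, group)`.
#'
#' @param cfg a [synth_config()].
#' @param subject_id subject identifier (also the substream key).
#' @param group one of `"HC"`, `"PD_OFF"`, `"PD_ON"`, `"PD"`.
#' @return An `eeg_recording`.
#' @export
simulate_recording <- function(cfg, subject_id, group) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!group %in% GROUP_LEVELS) stopf("unknown group '%s'", group)
  preset <- cfg$preset
  fs <- preset$fs
  n <- round(fs * cfg$duration_s)
  bands <- eeg_bands()
  mult <- group_multipliers(cfg, group)
  # subject-level random effects come from a subject-only substream so the
  # same subject keeps its traits across sessions (PD_OFF and PD_ON):
  # a per-band amplitude effect plus a fixed per-channel gain profile (an
  # individual "topography", at half the log-scale SD), which is what makes
  # subjects recognisable to epoch-level classifiers.
  sfx <- with_seed(substream_seed(cfg$seed, "subject", subject_id), {
    list(band = exp(rnorm(nrow(bands), 0, cfg$subject_sd)),
         chan = exp(rnorm(preset$n_channels, 0, cfg$subject_sd / 2)))
  })
  amps <- cfg$band_amplitudes * sfx$band * mult
  sig <- with_seed(substream_seed(cfg$seed, "signal", subject_id, group), {
    out <- matrix(0, nrow = preset$n_channels, ncol = n)
    for (ch in seq_len(preset$n_channels)) {
      tr <- numeric(n)
      for (b in seq_len(nrow(bands))) {
        if (amps[b] > 0)
          tr <- tr + amps[b] * sfx$chan[ch] *
            band_limited_noise(n, fs, bands$low_hz[b], bands$high_hz[b])
      }
      if (cfg$pink_noise_amp > 0)
        tr <- tr + cfg$pink_noise_amp * pink_noise(n, fs)
      if (cfg$white_noise_amp > 0)
        tr <- tr + cfg$white_noise_amp * rnorm(n)
      out[ch, ] <- tr
    }
    out
  })
  rec <- new_recording(sig, fs, preset$channels,
                       subject_id = subject_id, group = group)
  if (cfg$blink_rate > 0 && cfg$blink_amp > 0)
    rec <- inject_blinks(rec, cfg$blink_rate, cfg$blink_amp,
                         seed = substream_seed(cfg$seed, "blinks",
                                               subject_id, group))
  rec
}

#' Inject stereotyped eye-blink artifacts
#'
#' Adds 300 ms raised-cosine transients at Poisson-distributed times: full
#' amplitude on the frontopolar channels Fp1 and Fp2 and exponentially
#' attenuated with scalp distance from the frontal pole elsewhere, mimicking
#' the spatial signature that makes Fp1/Fp2 usable as ocular proxies for
#' artifact rejection.
#'
#' @param rec an `eeg_recording` whose montage contains Fp1 and Fp2.
#' @param rate blink rate (events/min).
#' @param amp peak amplitude on Fp1/Fp2 (uV).
#' @param seed integer seed for the Poisson event times.
#' @return The recording with blinks added.
#' @export
inject_blinks <- function(rec, rate, amp, seed = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  i1 <- channel_index(rec, "Fp1"); i2 <- channel_index(rec, "Fp2")
  if (is.na(i1) || is.na(i2))
    stopf("montage lacks Fp1/Fp2; blink injection needs the ocular proxies")
  if (rate <= 0 || amp <= 0) return(rec)
  n <- ncol(rec$signal)
  fs <- rec$fs
  blen <- round(0.3 * fs)
  bump <- amp * 0.5 * (1 - cos(2 * pi * seq(0, blen - 1) / (blen - 1)))
  # spatial profile: 1 on Fp1/Fp2, exp(-excess frontal distance / 0.35)
  xy <- CHANNEL_XY[match(normalize_channel(rec$channel_names),
                         normalize_channel(rownames(CHANNEL_XY))), ,
                   drop = FALSE]
  d <- sqrt((xy[, 1] - 0)^2 + (xy[, 2] - 1)^2)
  d[is.na(d)] <- 2                         # unknown channels: far away
  dfp <- mean(d[c(i1, i2)])
  atten <- exp(-pmax(0, d - dfp) / 0.35)
  atten[c(i1, i2)] <- 1
  starts <- with_seed(seed, {
    k <- rpois(1, rate * rec$duration_s / 60)
    if (k == 0) integer() else sort(floor(runif(k, 0, n - blen)))
  })
  out <- rec
  for (s in starts) {
    idx <- (s + 1):(s + blen)
    out$signal[, idx] <- out$signal[, idx] + outer(atten, bump)
  }
  out$n_blinks <- length(starts)
  out
}

#' Simulate a full cohort
#'
#' For the `dataset1` geometry each patient contributes two sessions
#' (`PD_OFF` and `PD_ON`, the latter with multipliers pulled halfway toward
#' 1 to mimic medication); `dataset2` patients contribute one session of
#' unspecified medication state (group `"PD"`). Controls contribute one
#' recording each. With the preset cohort sizes this yields 46 recordings
#' for `dataset1` (16 HC + 2 x 15 PD) and 28 for `dataset2`.
#'
#' @param cfg a [synth_config()].
#' @return A list of `eeg_recording`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$n_pd < 0 || cfg$n_hc < 0) stopf("cohort sizes must be >= 0")
  recs <- list()
  for (i in seq_len(cfg$n_hc))
    recs[[length(recs) + 1]] <-
      simulate_recording(cfg, sprintf("hc%02d", i), "HC")
  for (i in seq_len(cfg$n_pd)) {
    sid <- sprintf("pd%02d", i)
    if (cfg$preset$name == "dataset1") {
      recs[[length(recs) + 1]] <- simulate_recording(cfg, sid, "PD_OFF")
      recs[[length(recs) + 1]] <- simulate_recording(cfg, sid, "PD_ON")
    } else {
      recs[[length(recs) + 1]] <- simulate_recording(cfg, sid, "PD")
    }
  }
  recs
}
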