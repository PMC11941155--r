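# Shared fixtures. Heavier synthetic cohorts are memoised so several test
# files can reuse them within one run.

mini_channels <- c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "O1", "Oz")

# Small white-noise recording on an 8-channel montage.
mini_rec <- function(fs = 128, secs = 4, seed = 1, group = "HC",
                     subject_id = "s1", channels = mini_channels) {
  set.seed(seed)
  new_recording(matrix(rnorm(length(channels) * round(fs * secs)),
                       nrow = length(channels)),
                fs, channels, subject_id = subject_id, group = group)
}

# Pure sinusoid on every channel.
sine_rec <- function(freq, fs = 256, secs = 4, nch = 2, amp = 1,
                     channels = mini_channels[seq_len(nch)]) {
  t <- seq_len(round(fs * secs)) / fs
  new_recording(matrix(rep(amp * sin(2 * pi * freq * t), each = nch),
                       nrow = nch),
                fs, channels)
}

# Feature matrix built directly from a values matrix (single pseudo-band).
toy_features <- function(values, labels, subject_ids = NULL,
                         band = "gamma", standardized = TRUE) {
  values <- as.matrix(values)
  n <- nrow(values)
  new_features(values,
               feature_names = paste(band, paste0("ch", seq_len(ncol(values))),
                                     sep = "_"),
               labels = labels,
               subject_ids = subject_ids %||% paste0("s", seq_len(n)),
               groups = ifelse(labels == 1, "PD", "HC"),
               layout = "per_band", bands = band,
               channels = paste0("ch", seq_len(ncol(values))),
               standardized = standardized)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Strongly planted dataset2-geometry cohort (theta x2, beta/gamma x0.4, low
# subject heterogeneity), scaled to 20 s per recording for test budgets.
planted_band_features <- function() {
  memo("planted", {
    cfg <- synth_config(dataset_preset("dataset2"), n_pd = 8, n_hc = 8,
                        duration_s = 20, seed = 101,
                        pd_band_multipliers = c(delta = 1, theta = 2,
                                                alpha = 1, beta = 0.4,
                                                gamma = 0.4),
                        subject_sd = 0.05, blink_rate = 0)
    cohort_band_features(simulate_cohort(cfg), ica = FALSE)
  })
}

# Same planted effect under strong subject heterogeneity.
hetero_band_features <- function() {
  memo("hetero", {
    cfg <- synth_config(dataset_preset("dataset2"), n_pd = 8, n_hc = 8,
                        duration_s = 20, seed = 13,
                        pd_band_multipliers = c(delta = 1, theta = 2,
                                                alpha = 1, beta = 0.4,
                                                gamma = 0.4),
                        subject_sd = 1.2, blink_rate = 0)
    cohort_band_features(simulate_cohort(cfg), ica = FALSE)
  })
}

# FFT amplitude of a trace at one frequency (independent spectral oracle).
fft_amp <- function(x, freq, fs) {
  n <- length(x)
  2 * Mod(fft(x)[round(freq * n / fs) + 1]) / n
}
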