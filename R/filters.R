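# Zero-phase Butterworth band-pass filtering.
#
# The digital filter is designed from the analog Butterworth prototype:
# lowpass prototype poles -> lowpass-to-bandpass transform -> bilinear
# transform (with edge prewarping) -> second-order sections. Filtering runs
# forward and backward over each trace (compiled biquad cascade), so the
# net response is zero-phase with squared magnitude.

# Second-order sections for an order-`order` Butterworth band-pass.
# Returns list(sos = n_sections x 6 matrix, gain = scalar).
butter_bandpass_sos <- function(low_hz, high_hz, fs, order = 6) {
  if (!(low_hz > 0) || !(low_hz < high_hz))
    stopf("band edges must satisfy 0 < low < high (got %g, %g)",
          low_hz, high_hz)
  if (high_hz >= fs / 2)
    stopf("upper edge %g Hz violates Nyquist (fs/2 = %g Hz)", high_hz, fs / 2)
  n <- as.integer(order)
  fs2 <- 2 * fs
  # prewarped analog edge frequencies (rad/s)
  w1 <- fs2 * tan(pi * low_hz / fs)
  w2 <- fs2 * tan(pi * high_hz / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  # analog lowpass prototype poles (unit cutoff, left half-plane)
  k <- seq_len(n)
  p_lp <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # lowpass -> bandpass: each prototype pole maps to a conjugate-ish pair
  p_s <- p_lp * bw / 2
  p_bp <- c(p_s + sqrt(p_s^2 - w0^2), p_s - sqrt(p_s^2 - w0^2))
  gain_s <- bw^n                       # from the n analog zeros at s = 0
  # bilinear transform
  p_z <- (fs2 + p_bp) / (fs2 - p_bp)
  # n analog zeros at 0 -> z = +1; degree deficit adds n zeros at z = -1
  gain_z <- gain_s * Re(fs2^n / prod(fs2 - p_bp))
  # pair conjugate poles into sections; each section gets zeros (+1, -1),
  # i.e. numerator z^2 - 1. Order sections with poles farthest from the
  # unit circle first for numerical headroom.
  pu <- p_z[Im(p_z) >= 0]
  pu <- pu[order(abs(pu))]
  sos <- t(vapply(pu, function(p) {
    c(1, 0, -1, 1, -2 * Re(p), Mod(p)^2)
  }, numeric(6)))
  list(sos = sos, gain = gain_z)
}

# Evaluate the (single-pass) SOS frequency response at frequencies f (Hz).
sos_freq_response <- function(filt, f, fs) {
  z <- exp(-2i * pi * f / fs)
  h <- rep(complex(real = filt$gain), length(f))
  for (s in seq_len(nrow(filt$sos))) {
    b <- filt$sos[s, 1:3]; a <- filt$sos[s, 4:6]
    h <- h * (b[1] + b[2] * z + b[3] * z^2) / (a[1] + a[2] * z + a[3] * z^2)
  }
  h
}

#' Zero-phase band-pass filter a recording
#'
#' Applies an order-6 Butterworth band-pass forward and backward over every
#' channel (zero phase, length preserved). The broadband analysis filter is
#' 0.5--50 Hz; the same routine realises the per-band filters of
#' [decompose_bands()].
#'
#' @param rec an `eeg_recording`.
#' @param low_hz,high_hz band edges in Hz; `0 < low < high < fs/2`.
#' @param order Butterworth order of each pass (default 6, which keeps the
#'   passband within about 0.5 dB and attenuates 60 Hz by more than 20 dB
#'   after the two passes).
#' @return A filtered `eeg_recording` of identical shape.
#' @examples
#' rec <- new_recording(matrix(rnorm(1024), 2), 256, c("Fp1", "Fp2"))
#' filt <- bandpass(rec, 0.5, 50)
#' dim(filt$signal)
#' @export
bandpass <- function(rec, low_hz, high_hz, order = 6) {
  stopifnot(inherits(rec, "eeg_recording"))
  filt <- butter_bandpass_sos(low_hz, high_hz, rec$fs, order)
  # pad long enough for the slowest transient (the low edge), capped at n-1
  n <- ncol(rec$signal)
  out <- rec
  out$signal <- t(apply(rec$signal, 1, function(tr)
    filtfilt_padded(filt, tr, pad = min(n - 1, ceiling(3 * rec$fs / low_hz)))))
  rownames(out$signal) <- rec$channel_names
  out
}

# filtfilt with an explicit pad length (odd reflection at both ends).
filtfilt_padded <- function(filt, x, pad) {
  n <- length(x)
  pad <- max(1L, min(n - 1L, as.integer(pad)))
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- sosfilt_cpp(filt$sos, ext * filt$gain)
  y <- rev(sosfilt_cpp(filt$sos, rev(y) * filt$gain))
  y[(pad + 1):(pad + n)]
}

#' Split a recording into band-limited copies
#'
#' Filters the recording once per frequency band, yielding one band-limited
#' copy per row of `bands` (by default the five canonical bands of
#' [eeg_bands()]).
#'
#' @param rec an `eeg_recording`.
#' @param bands a data.frame like [eeg_bands()] output.
#' @return A named list of `eeg_recording`, one per band, in `bands` order.
#' @export
decompose_bands <- function(rec, bands = eeg_bands()) {
  stopifnot(inherits(rec, "eeg_recording"))
  out <- lapply(seq_len(nrow(bands)), function(i)
    bandpass(rec, bands$low_hz[i], bands$high_hz[i]))
  names(out) <- bands$name
  out
}
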