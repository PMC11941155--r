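# Welch power spectral density estimation.
#
# The PSD of each channel is estimated by averaging modified periodograms
# of Hann-windowed, overlapping sub-segments (Welch's method). One-sided
# density scaling is used, so integrating power over frequency recovers the
# mean squared amplitude of the trace (Parseval).

# Core: x is a window_len x m matrix whose columns are traces to transform;
# each column set belongs to (trace, segment) pairs prepared by the caller.
# Returns the one-sided density matrix (n_freq x m) WITHOUT segment
# averaging (the caller averages).
periodogram_cols <- function(xw, fs, wsum2) {
  n <- nrow(xw)
  X <- stats::mvfft(xw)
  nf <- n %/% 2 + 1
  P <- (Mod(X[seq_len(nf), , drop = FALSE])^2) / (fs * wsum2)
  # one-sided: double everything except DC and (for even n) Nyquist
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (n %% 2 == 0) dbl[nf] <- 1
  P * dbl
}

# Segment start offsets (0-based) for Welch on traces of length ns.
welch_offsets <- function(ns, window_len, overlap_frac) {
  hop <- max(1L, as.integer(round(window_len * (1 - overlap_frac))))
  seq.int(0L, ns - window_len, by = hop)
}

#' Welch power spectral density of one epoch
#'
#' Averages Hann-windowed, overlapping modified periodograms per channel.
#' With the defaults (window of half the epoch, 50% overlap) a 1-s epoch
#' yields three averaged segments and a 2 Hz frequency grid, the coarsest
#' grid on which the delta band (1--4 Hz) still owns a bin.
#'
#' @param epoch channels x samples numeric matrix (one epoch), or a plain
#'   vector for a single channel.
#' @param fs sampling rate (Hz).
#' @param window_len sub-segment length in samples (default `round(fs/2)`).
#' @param overlap_frac fractional overlap between sub-segments in `[0, 1)`
#'   (default 0.5).
#' @param window `"hann"` (default) or `"rect"`; the rectangular window with
#'   `window_len` equal to the full epoch reduces Welch to the plain
#'   periodogram.
#' @return An object of class `eeg_spectrum`: list with `freqs` (Hz) and
#'   `power` (channels x freqs, one-sided density in uV^2/Hz).
#' @export
welch_psd <- function(epoch, fs, window_len = round(fs / 2),
                      overlap_frac = 0.5, window = c("hann", "rect")) {
  window <- match.arg(window)
  if (is.vector(epoch)) epoch <- matrix(epoch, nrow = 1)
  ns <- ncol(epoch)
  window_len <- as.integer(window_len)
  if (window_len > ns)
    stopf("window_len %d exceeds epoch length %d", window_len, ns)
  if (!(overlap_frac >= 0 && overlap_frac < 1))
    stopf("overlap_frac must lie in [0, 1)")
  w <- if (window == "hann") {
    0.5 * (1 - cos(2 * pi * seq(0, window_len - 1) / window_len))
  } else rep(1, window_len)
  offs <- welch_offsets(ns, window_len, overlap_frac)
  nch <- nrow(epoch)
  # columns: channel-major blocks, one block per segment offset
  acc <- NULL
  for (o in offs) {
    seg <- t(epoch[, (o + 1):(o + window_len), drop = FALSE]) * w
    P <- periodogram_cols(seg, fs, sum(w^2))
    acc <- if (is.null(acc)) P else acc + P
  }
  P <- acc / length(offs)
  freqs <- seq(0, by = fs / window_len, length.out = nrow(P))
  structure(list(freqs = freqs, power = t(P)), class = "eeg_spectrum")
}

#' Mean in-band spectral power
#'
#' Summarises a spectrum over a frequency band as the mean one-sided density
#' over bins with `low_hz <= f < high_hz` (half-open, so shared band edges
#' are counted exactly once across the canonical bands). The mean (rather
#' than the sum) makes the summary invariant to the frequency-grid
#' resolution.
#'
#' @param spec an `eeg_spectrum` from [welch_psd()].
#' @param band one-row band data.frame ([band_definition()] or a row of
#'   [eeg_bands()]).
#' @param summary `"mean"` (default) or `"sum"` over in-band bins.
#' @return Named numeric vector, one value per channel (uV^2/Hz for
#'   `"mean"`).
#' @export
band_power <- function(spec, band, summary = c("mean", "sum")) {
  summary <- match.arg(summary)
  sel <- spec$freqs >= band$low_hz & spec$freqs < band$high_hz
  if (!any(sel))
    stopf("band %s [%g, %g) has no bins on a %g Hz grid",
          band$name, band$low_hz, band$high_hz,
          diff(spec$freqs[1:2]))
  p <- spec$power[, sel, drop = FALSE]
  if (summary == "mean") rowMeans(p) else rowSums(p)
}
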