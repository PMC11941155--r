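# Recording container, dataset geometry presets and montage validation.

GROUP_LEVELS <- c("HC", "PD_OFF", "PD_ON", "PD")

DATASET1_CHANNELS <- c(
  "Fp1", "Fp2", "AF3", "AF4", "F3", "F4", "F7", "F8", "Fz",
  "FC1", "FC2", "FC5", "FC6", "C3", "C4", "Cz", "T7", "T8",
  "CP1", "CP2", "CP5", "CP6", "P3", "P4", "P7", "P8", "Pz",
  "PO3", "PO4", "O1", "O2", "Oz"
)

DATASET2_CHANNELS <- c(
  "Fp1", "AF3", "F7", "F3", "FC1", "FC5", "T7", "C3", "CP1", "CP5",
  "P7", "P3", "O1", "Oz", "O2", "P4", "P8", "CP6", "CP2", "C4",
  "T8", "FC6", "FC2", "F4", "F8", "AF4", "Fp2", "Fz", "Cz"
)

# Approximate 2D scalp positions (10-20 projection, unit head radius,
# x toward the right ear, y toward the nasion). Used only for spatial
# attenuation of simulated blink artifacts; not anatomically exact.
CHANNEL_XY <- local({
  m <- rbind(
    Fp1 = c(-0.31,  0.95), Fp2 = c( 0.31,  0.95),
    AF3 = c(-0.35,  0.78), AF4 = c( 0.35,  0.78),
    F7  = c(-0.81,  0.59), F3  = c(-0.55,  0.48), Fz = c(0,  0.50),
    F4  = c( 0.55,  0.48), F8  = c( 0.81,  0.59),
    FC5 = c(-0.77,  0.25), FC1 = c(-0.30,  0.25),
    FC2 = c( 0.30,  0.25), FC6 = c( 0.77,  0.25),
    T7  = c(-1.00,  0.00), C3  = c(-0.50,  0.00), Cz = c(0,  0.00),
    C4  = c( 0.50,  0.00), T8  = c( 1.00,  0.00),
    CP5 = c(-0.77, -0.25), CP1 = c(-0.30, -0.25),
    CP2 = c( 0.30, -0.25), CP6 = c( 0.77, -0.25),
    P7  = c(-0.81, -0.59), P3  = c(-0.55, -0.48), Pz = c(0, -0.50),
    P4  = c( 0.55, -0.48), P8  = c( 0.81, -0.59),
    PO3 = c(-0.35, -0.78), PO4 = c( 0.35, -0.78),
    O1  = c(-0.31, -0.95), Oz  = c( 0.00, -1.00), O2 = c(0.31, -0.95)
  )
  colnames(m) <- c("x", "y")
  m
})

# Normalize channel labels for matching: case-insensitive, reference
# suffixes ("-A1", "-REF", "-LE") and stray whitespace dropped.
normalize_channel <- function(x) {
  x <- toupper(trimws(x))
  sub("-[A-Z0-9]+$", "", x)
}

#' EEG recording container
#'
#' Bundles a channels-by-samples signal matrix (in microvolts) with its
#' sampling rate, ordered 10-20 channel labels and cohort metadata.
#'
#' @param signal numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz; must exceed 100 Hz so the 0.5--50 Hz
#'   analysis band sits comfortably below Nyquist.
#' @param channel_names character vector of unique channel labels, one per
#'   signal row.
#' @param subject_id opaque subject identifier.
#' @param group cohort label, one of `"HC"`, `"PD_OFF"`, `"PD_ON"` or `"PD"`
#'   (the last for patients whose medication session is not specified, as in
#'   single-session datasets).
#' @return An object of class `eeg_recording` with fields `signal`, `fs`,
#'   `channel_names`, `subject_id`, `group` and `duration_s`.
#' @export
new_recording <- function(signal, fs, channel_names,
                          subject_id = "anon", group = "HC") {
  signal <- as.matrix(signal)
  if (!is.numeric(signal)) stopf("signal must be a numeric matrix")
  if (length(channel_names) != nrow(signal))
    stopf("%d channel names for %d signal rows",
          length(channel_names), nrow(signal))
  if (anyDuplicated(normalize_channel(channel_names)))
    stopf("duplicate channel labels: %s",
          paste(unique(channel_names[duplicated(normalize_channel(channel_names))]),
                collapse = ", "))
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 100)
    stopf("fs must be a single rate > 100 Hz (Nyquist must cover 50 Hz)")
  if (!group %in% GROUP_LEVELS)
    stopf("group must be one of %s", paste(GROUP_LEVELS, collapse = ", "))
  rownames(signal) <- channel_names
  structure(
    list(signal = signal, fs = as.numeric(fs),
         channel_names = as.character(channel_names),
         subject_id = as.character(subject_id), group = group,
         duration_s = ncol(signal) / fs),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s [%s]: %d ch x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$group, nrow(x$signal), ncol(x$signal),
              x$fs, x$duration_s))
  invisible(x)
}

#' Dataset geometry presets
#'
#' Two fixed acquisition geometries: `dataset1` is a 32-channel, 512 Hz
#' montage analysed over its first 180 s (180 one-second epochs);
#' `dataset2` is a 29-channel, 500 Hz montage analysed over its first 120 s
#' (120 epochs).
#'
#' @param name `"dataset1"` or `"dataset2"`.
#' @return A list with `name`, `n_channels`, `fs`, `crop_s`, `n_epochs` and
#'   the ordered `channels` vector.
#' @export
dataset_preset <- function(name = c("dataset1", "dataset2")) {
  name <- match.arg(name)
  if (name == "dataset1")
    list(name = "dataset1", n_channels = 32L, fs = 512, crop_s = 180,
         n_epochs = 180L, channels = DATASET1_CHANNELS)
  else
    list(name = "dataset2", n_channels = 29L, fs = 500, crop_s = 120,
         n_epochs = 120L, channels = DATASET2_CHANNELS)
}

#' Check a recording against a dataset preset
#'
#' Pure reporting helper: compares channel count, sampling rate and the
#' montage name set (case-insensitively, ignoring reference suffixes)
#' against a preset and describes every mismatch.
#'
#' @param rec an [new_recording()] object.
#' @param preset a [dataset_preset()] list.
#' @return Character vector of human-readable discrepancies; empty when the
#'   recording conforms.
#' @export
validate_montage <- function(rec, preset) {
  stopifnot(inherits(rec, "eeg_recording"))
  out <- character()
  if (nrow(rec$signal) != preset$n_channels)
    out <- c(out, sprintf("channel count %d differs from preset %s (%d)",
                          nrow(rec$signal), preset$name, preset$n_channels))
  if (!isTRUE(all.equal(rec$fs, preset$fs)))
    out <- c(out, sprintf("sampling rate %g Hz differs from preset %s (%g Hz)",
                          rec$fs, preset$name, preset$fs))
  have <- normalize_channel(rec$channel_names)
  want <- normalize_channel(preset$channels)
  missing <- preset$channels[!(want %in% have)]
  extra <- rec$channel_names[!(have %in% want)]
  if (length(missing))
    out <- c(out, sprintf("missing channel(s): %s",
                          paste(missing, collapse = ", ")))
  if (length(extra))
    out <- c(out, sprintf("unexpected channel(s): %s",
                          paste(extra, collapse = ", ")))
  out
}

# Index of a named channel in a recording (normalized match), or NA.
channel_index <- function(rec, name) {
  match(normalize_channel(name), normalize_channel(rec$channel_names))
}
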