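# Cropping and fixed-length segmentation into labelled 1-s epochs.

#' Crop a recording to its first seconds
#'
#' @param rec an `eeg_recording`.
#' @param seconds duration to keep from the start.
#' @return The cropped recording.
#' @export
crop <- function(rec, seconds) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- round(rec$fs * seconds)
  if (n > ncol(rec$signal))
    stopf("recording holds %.3f s but %.3f s requested",
          rec$duration_s, seconds)
  out <- rec
  out$signal <- rec$signal[, seq_len(n), drop = FALSE]
  out$duration_s <- n / rec$fs
  out
}

# 0/1 epoch label from a cohort group: controls are 0, patients 1.
group_label <- function(group) as.integer(group != "HC")

#' Segment a recording into contiguous fixed-length epochs
#'
#' Takes the first `n_epochs` non-overlapping windows of `epoch_len_s`
#' seconds, exactly tiling the front of the recording. Every epoch inherits
#' the recording's subject id and a binary class label (healthy controls 0,
#' patients 1).
#'
#' @param rec an `eeg_recording`.
#' @param epoch_len_s epoch length in seconds (default 1).
#' @param n_epochs number of epochs; defaults to as many full epochs as fit.
#' @return An object of class `eeg_epochs`: list with `data` (epochs x
#'   channels x samples array), `fs`, `epoch_len_s`, `channel_names`,
#'   `labels`, `subject_ids` and `groups`.
#' @export
segment <- function(rec, epoch_len_s = 1, n_epochs = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  spe <- round(rec$fs * epoch_len_s)
  n_epochs <- as.integer(n_epochs %||% (ncol(rec$signal) %/% spe))
  if (n_epochs < 1) stopf("n_epochs must be >= 1")
  need <- n_epochs * spe
  if (need > ncol(rec$signal))
    stopf("%d epochs of %g s need %d samples; recording has %d",
          n_epochs, epoch_len_s, need, ncol(rec$signal))
  d <- array(0, dim = c(n_epochs, nrow(rec$signal), spe))
  for (e in seq_len(n_epochs))
    d[e, , ] <- rec$signal[, ((e - 1) * spe + 1):(e * spe)]
  new_epochs(d, rec$fs, epoch_len_s, rec$channel_names,
             labels = rep(group_label(rec$group), n_epochs),
             subject_ids = rep(rec$subject_id, n_epochs),
             groups = rep(rec$group, n_epochs))
}

new_epochs <- function(data, fs, epoch_len_s, channel_names,
                       labels, subject_ids, groups) {
  stopifnot(length(dim(data)) == 3,
            length(labels) == dim(data)[1],
            length(subject_ids) == dim(data)[1],
            length(groups) == dim(data)[1],
            length(channel_names) == dim(data)[2])
  structure(list(data = data, fs = fs, epoch_len_s = epoch_len_s,
                 channel_names = channel_names,
                 labels = as.integer(labels),
                 subject_ids = as.character(subject_ids),
                 groups = as.character(groups)),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d epochs x %d ch x %d samples @ %g Hz (%d subjects)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs,
              length(unique(x$subject_ids))))
  invisible(x)
}

#' Concatenate epoch arrays along the epoch axis
#'
#' @param ... `eeg_epochs` objects with identical geometry.
#' @return A single combined `eeg_epochs`.
#' @export
bind_epochs <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && is.list(xs[[1]]) && !inherits(xs[[1]], "eeg_epochs"))
    xs <- xs[[1]]
  stopifnot(length(xs) >= 1)
  ref <- xs[[1]]
  for (x in xs[-1]) {
    if (!identical(dim(x$data)[2:3], dim(ref$data)[2:3]) ||
        !isTRUE(all.equal(x$fs, ref$fs)))
      stopf("epoch arrays have mismatched geometry")
  }
  d <- array(0, dim = c(sum(vapply(xs, function(x) dim(x$data)[1], 0L)),
                        dim(ref$data)[2], dim(ref$data)[3]))
  at <- 0L
  for (x in xs) {
    ne <- dim(x$data)[1]
    d[at + seq_len(ne), , ] <- x$data
    at <- at + ne
  }
  new_epochs(d, ref$fs, ref$epoch_len_s, ref$channel_names,
             labels = unlist(lapply(xs, `[[`, "labels")),
             subject_ids = unlist(lapply(xs, `[[`, "subject_ids")),
             groups = unlist(lapply(xs, `[[`, "groups")))
}
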