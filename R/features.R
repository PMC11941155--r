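# Band-power feature matrices and train-only standardization.

#' Feature matrix container
#'
#' Epochs-by-features matrix of Welch band powers with epoch metadata.
#' `per_band` layout holds one band's channels; `stacked` layout holds all
#' five bands concatenated band-major (delta channels, theta channels, ...)
#' so each row reshapes losslessly to a bands x channels map.
#'
#' @param values epochs x features numeric matrix.
#' @param feature_names `"<band>_<channel>"` column names.
#' @param labels,subject_ids,groups per-epoch metadata.
#' @param layout `"per_band"` or `"stacked"`.
#' @param bands band names present, in column-block order.
#' @param channels channel names per block.
#' @param standardized logical flag (set by [apply_standardizer()]).
#' @return An object of class `eeg_features`.
#' @export
new_features <- function(values, feature_names, labels, subject_ids, groups,
                         layout = c("per_band", "stacked"), bands, channels,
                         standardized = FALSE) {
  layout <- match.arg(layout)
  values <- as.matrix(values)
  if (ncol(values) != length(feature_names))
    stopf("%d feature names for %d columns", length(feature_names),
          ncol(values))
  if (nrow(values) != length(labels) || nrow(values) != length(subject_ids))
    stopf("labels/subject_ids must match the %d epochs", nrow(values))
  colnames(values) <- feature_names
  structure(list(values = values, feature_names = feature_names,
                 labels = as.integer(labels),
                 subject_ids = as.character(subject_ids),
                 groups = as.character(groups), layout = layout,
                 bands = bands, channels = channels,
                 standardized = standardized),
            class = "eeg_features")
}

#' @export
print.eeg_features <- function(x, ...) {
  cat(sprintf("<eeg_features %s> %d epochs x %d features (%s)%s\n",
              x$layout, nrow(x$values), ncol(x$values),
              paste(x$bands, collapse = "+"),
              if (x$standardized) " [standardized]" else ""))
  invisible(x)
}

# Welch band power for every (epoch, channel) of a band-filtered epoch
# array, vectorised over epochs in chunks to bound the FFT workspace.
welch_band_power_array <- function(epochs, band, window_len, overlap_frac,
                                   summary = "mean", chunk = 256L) {
  ne <- dim(epochs$data)[1]; nch <- dim(epochs$data)[2]
  ns <- dim(epochs$data)[3]
  w <- 0.5 * (1 - cos(2 * pi * seq(0, window_len - 1) / window_len))
  offs <- welch_offsets(ns, window_len, overlap_frac)
  nf <- window_len %/% 2 + 1
  freqs <- seq(0, by = epochs$fs / window_len, length.out = nf)
  sel <- freqs >= band$low_hz & freqs < band$high_hz
  if (!any(sel))
    stopf("band %s [%g, %g) has no bins on a %g Hz grid",
          band$name, band$low_hz, band$high_hz, epochs$fs / window_len)
  out <- matrix(0, ne, nch)
  for (start in seq(1L, ne, by = chunk)) {
    ix <- start:min(ne, start + chunk - 1L)
    # samples x (channel, epoch) columns
    x <- matrix(aperm(epochs$data[ix, , , drop = FALSE], c(3, 2, 1)),
                nrow = ns)
    acc <- 0
    for (o in offs) {
      seg <- x[(o + 1):(o + window_len), , drop = FALSE] * w
      acc <- acc + periodogram_cols(seg, epochs$fs, sum(w^2))
    }
    P <- acc / length(offs)
    bp <- if (summary == "mean") colMeans(P[sel, , drop = FALSE])
          else colSums(P[sel, , drop = FALSE])
    out[ix, ] <- matrix(bp, nrow = length(ix), ncol = nch, byrow = TRUE)
  }
  out
}

#' Per-band Welch band-power features
#'
#' One row per epoch and one column per channel: the mean Welch PSD of that
#' epoch over the band's frequency bins. The epochs must already be
#' band-filtered for `band` (decompose-then-measure); the in-band masking
#' of a broadband spectrum gives near-identical values, which is exercised
#' as a test rather than relied upon.
#'
#' @param epochs an `eeg_epochs` array, band-filtered for `band`.
#' @param band one-row band data.frame.
#' @param window_len,overlap_frac Welch parameters (defaults: half the
#'   epoch's sampling rate and 50%, i.e. three averaged segments per 1-s
#'   epoch on a 2 Hz grid).
#' @param summary `"mean"` (default) or `"sum"` over in-band bins.
#' @param log_power apply `log10` to the band powers (default FALSE; the
#'   reference pipeline standardizes raw powers).
#' @return A `per_band` `eeg_features`.
#' @export
build_band_features <- function(epochs, band,
                                window_len = round(epochs$fs / 2),
                                overlap_frac = 0.5, summary = c("mean", "sum"),
                                log_power = FALSE) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  summary <- match.arg(summary)
  if (window_len > dim(epochs$data)[3])
    stopf("window_len %d exceeds epoch length %d", window_len,
          dim(epochs$data)[3])
  vals <- welch_band_power_array(epochs, band, as.integer(window_len),
                                 overlap_frac, summary)
  if (log_power) vals <- log10(pmax(vals, .Machine$double.xmin))
  new_features(vals,
               feature_names = paste(band$name, epochs$channel_names,
                                     sep = "_"),
               labels = epochs$labels, subject_ids = epochs$subject_ids,
               groups = epochs$groups, layout = "per_band",
               bands = band$name, channels = epochs$channel_names)
}

#' Stack per-band feature matrices band-major
#'
#' Concatenates the five per-band matrices into the stacked layout whose
#' rows reshape to a bands x channels map ([features_to_map()]); for the
#' 32-channel geometry this gives 160 columns, for the 29-channel geometry
#' 145.
#'
#' @param per_band named list of `per_band` `eeg_features`, one per band.
#'   Stacking order follows the canonical band order for canonical names,
#'   else the list order.
#' @return A `stacked` `eeg_features`.
#' @export
stack_bands <- function(per_band) {
  stopifnot(is.list(per_band), length(per_band) >= 1)
  ord <- names(per_band)
  if (all(ord %in% band_order)) ord <- band_order[band_order %in% ord]
  per_band <- per_band[ord]
  ref <- per_band[[1]]
  for (fm in per_band[-1]) {
    if (nrow(fm$values) != nrow(ref$values) ||
        !identical(fm$labels, ref$labels) ||
        !identical(fm$subject_ids, ref$subject_ids))
      stopf("per-band matrices disagree on epochs, labels or subjects")
    if (!identical(fm$channels, ref$channels))
      stopf("per-band matrices disagree on channel sets")
  }
  new_features(do.call(cbind, lapply(per_band, `[[`, "values")),
               feature_names = unlist(lapply(per_band, `[[`,
                                             "feature_names"),
                                      use.names = FALSE),
               labels = ref$labels, subject_ids = ref$subject_ids,
               groups = ref$groups, layout = "stacked",
               bands = ord, channels = ref$channels)
}

#' Split a stacked matrix back into per-band matrices
#'
#' Inverse of [stack_bands()] on values and names.
#'
#' @param fm a `stacked` `eeg_features`.
#' @return Named list of `per_band` `eeg_features`.
#' @export
unstack_bands <- function(fm) {
  stopifnot(inherits(fm, "eeg_features"), fm$layout == "stacked")
  nch <- length(fm$channels)
  out <- lapply(seq_along(fm$bands), function(b) {
    cols <- (b - 1) * nch + seq_len(nch)
    new_features(fm$values[, cols, drop = FALSE],
                 feature_names = fm$feature_names[cols],
                 labels = fm$labels, subject_ids = fm$subject_ids,
                 groups = fm$groups, layout = "per_band",
                 bands = fm$bands[b], channels = fm$channels,
                 standardized = fm$standardized)
  })
  names(out) <- fm$bands
  out
}

#' Reshape one stacked row to a bands x channels map
#'
#' @param fm a `stacked` `eeg_features`.
#' @param epoch row index.
#' @return bands x channels numeric matrix with dimnames.
#' @export
features_to_map <- function(fm, epoch) {
  stopifnot(inherits(fm, "eeg_features"), fm$layout == "stacked")
  m <- matrix(fm$values[epoch, ], nrow = length(fm$bands), byrow = TRUE,
              dimnames = list(fm$bands, fm$channels))
  m
}

#' Fit / apply a train-only column standardizer
#'
#' Per-column z-scoring fitted on the training rows only (mean 0, SD 1) and
#' applied unchanged to held-out rows. Zero-variance training columns are
#' mapped to 0 with a warning.
#'
#' @param train an `eeg_features` (training rows, at least 2).
#' @return `fit_standardizer` returns an `eeg_scaler`;
#'   `apply_standardizer` returns the transformed `eeg_features`.
#' @export
fit_standardizer <- function(train) {
  stopifnot(inherits(train, "eeg_features"))
  if (nrow(train$values) < 2) stopf("standardizer needs >= 2 training rows")
  mu <- colMeans(train$values)
  sdv <- apply(train$values, 2, stats::sd)
  if (any(sdv == 0)) {
    warning(sprintf("%d zero-variance column(s) will be mapped to 0",
                    sum(sdv == 0)), call. = FALSE)
  }
  structure(list(mean = mu, sd = sdv, names = train$feature_names),
            class = "eeg_scaler")
}

#' @rdname fit_standardizer
#' @param scaler an `eeg_scaler` from [fit_standardizer()].
#' @param fm features to transform (same columns as the training matrix).
#' @export
apply_standardizer <- function(scaler, fm) {
  if (!inherits(scaler, "eeg_scaler"))
    stopf("apply_standardizer needs a fitted eeg_scaler")
  stopifnot(inherits(fm, "eeg_features"))
  if (!identical(scaler$names, fm$feature_names))
    stopf("scaler was fitted on different feature columns")
  out <- fm
  sdv <- ifelse(scaler$sd == 0, Inf, scaler$sd)   # zero-variance -> 0
  out$values <- sweep(sweep(fm$values, 2, scaler$mean), 2, sdv, "/")
  colnames(out$values) <- fm$feature_names
  out$standardized <- TRUE
  out
}
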