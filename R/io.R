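# On-disk interchange: EDF, BrainVision, plain matrix + JSON sidecar, and
# delimited feature tables. Cohort metadata (subject id, group) is not part
# of the EDF/BrainVision headers, so it travels in a JSON sidecar
# ("<path>.json") or explicit arguments.

pad_field <- function(x, width) {
  x <- as.character(x)
  width <- rep_len(width, length(x))
  vapply(seq_along(x), function(i)
    sprintf("%-*s", width[i], substr(x[i], 1, width[i])), "")
}

#' Write a recording as 16-bit EDF
#'
#' Standard EDF with 1-s data records; the sampling rate must therefore be
#' an integer and the signal is truncated to a whole number of seconds.
#' Amplitudes are quantised to 16 bits over each channel's physical range.
#'
#' @param rec an `eeg_recording`.
#' @param path output file path.
#' @param sidecar write `<path>.json` with subject id and group
#'   (default TRUE).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, sidecar = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs != round(fs)) stopf("EDF writer needs an integer sampling rate")
  nrec <- floor(ncol(rec$signal) / fs)
  if (nrec < 1) stopf("recording shorter than one EDF record (1 s)")
  ns <- nrow(rec$signal)
  sig <- rec$signal[, seq_len(nrec * fs), drop = FALSE]
  pmin_ <- apply(sig, 1, min); pmax_ <- apply(sig, 1, max)
  span <- pmax(pmax_ - pmin_, 1e-6)
  pmin_ <- pmin_ - 0.001 * span; pmax_ <- pmax_ + 0.001 * span
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field(rec$subject_id, 80),
    pad_field(sprintf("group=%s", rec$group), 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (1 + ns), 8),
    pad_field("", 44),
    pad_field(nrec, 8),
    pad_field(1, 8),
    pad_field(ns, 4),
    paste0(pad_field(rec$channel_names, rep(16, ns)), collapse = ""),
    paste0(pad_field(rep("", ns), rep(80, ns)), collapse = ""),
    paste0(pad_field(rep("uV", ns), rep(8, ns)), collapse = ""),
    paste0(pad_field(sprintf("%.6g", pmin_), rep(8, ns)), collapse = ""),
    paste0(pad_field(sprintf("%.6g", pmax_), rep(8, ns)), collapse = ""),
    paste0(pad_field(rep(-32768, ns), rep(8, ns)), collapse = ""),
    paste0(pad_field(rep(32767, ns), rep(8, ns)), collapse = ""),
    paste0(pad_field(rep("", ns), rep(80, ns)), collapse = ""),
    paste0(pad_field(rep(fs, ns), rep(8, ns)), collapse = ""),
    paste0(pad_field(rep("", ns), rep(32, ns)), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  scale <- (pmax_ - pmin_) / 65535
  for (r in seq_len(nrec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((sig[ch, cols] - pmin_[ch]) / scale[ch]) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con,
               size = 2, endian = "little")
    }
  }
  if (sidecar)
    jsonlite::write_json(list(subject_id = rec$subject_id, group = rec$group),
                         paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                      # version
  patient <- rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  nrec <- as.integer(rd(8))
  recdur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stopf("EDF header: bad signal count in '%s'", path)
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fld(16); fld(80); fld(8)
  pmin_ <- as.numeric(fld(8)); pmax_ <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8)); fld(32)
  if (any(!nzchar(labels)))
    stopf("EDF '%s' lacks channel labels; a montage is required", path)
  if (anyNA(pmin_) || anyNA(pmax_) || anyNA(dmin) || anyNA(dmax))
    stopf("EDF '%s': unparsable physical/digital range fields", path)
  if (length(unique(spr)) != 1)
    stopf("EDF '%s': mixed per-signal sampling rates are unsupported", path)
  fs <- spr[1] / recdur
  sig <- matrix(0, nrow = ns, ncol = nrec * spr[1])
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(nrec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[1], size = 2, endian = "little")
      sig[ch, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
        (dig - dmin[ch]) * scale[ch] + pmin_[ch]
    }
  }
  list(signal = sig, fs = fs, channel_names = labels, patient = patient)
}

#' Write a recording in BrainVision format
#'
#' Emits the `.vhdr`/`.vmrk`/`.eeg` triplet with multiplexed IEEE float32
#' samples in microvolts.
#'
#' @param rec an `eeg_recording`.
#' @param path path of the `.vhdr` file (companions are derived from it).
#' @param sidecar write `<path>.json` metadata sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
write_brainvision <- function(rec, path, sidecar = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"))
  base <- sub("\\.vhdr$", "", path)
  eeg <- paste0(base, ".eeg"); vmrk <- paste0(base, ".vmrk")
  ns <- nrow(rec$signal)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    sprintf("DataFile=%s", basename(eeg)),
    sprintf("MarkerFile=%s", basename(vmrk)),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", ns),
    sprintf("SamplingInterval=%.10g", 1e6 / rec$fs),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(ns), rec$channel_names)
  )
  writeLines(hdr, path, useBytes = TRUE)
  writeLines(c("Brain Vision Data Exchange Marker File, Version 1.0",
               "[Common Infos]", sprintf("DataFile=%s", basename(eeg))),
             vmrk)
  con <- file(eeg, "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$signal), con, size = 4, endian = "little")
  if (sidecar)
    jsonlite::write_json(list(subject_id = rec$subject_id, group = rec$group),
                         paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

read_brainvision <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  kv <- function(key) {
    hit <- grep(sprintf("^%s=", key), lines, value = TRUE)
    if (!length(hit)) stopf("BrainVision header '%s' lacks field %s",
                            path, key)
    sub(sprintf("^%s=", key), "", hit[1])
  }
  fmt <- toupper(kv("BinaryFormat"))
  if (!fmt %in% c("IEEE_FLOAT_32", "INT_16"))
    stopf("BrainVision '%s': unsupported BinaryFormat '%s'", path, fmt)
  if (toupper(kv("DataOrientation")) != "MULTIPLEXED")
    stopf("BrainVision '%s': only MULTIPLEXED orientation is supported", path)
  ns <- as.integer(kv("NumberOfChannels"))
  fs <- 1e6 / as.numeric(kv("SamplingInterval"))
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  if (length(ch_lines) != ns)
    stopf("BrainVision '%s': %d channel entries for %d channels",
          path, length(ch_lines), ns)
  parts <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",")
  labels <- vapply(parts, `[`, "", 1)
  res <- vapply(parts, function(p)
    if (length(p) >= 3 && nzchar(p[3])) as.numeric(p[3]) else 1, 0)
  eeg <- file.path(dirname(path), kv("DataFile"))
  sz <- file.info(eeg)$size
  con <- file(eeg, "rb")
  on.exit(close(con))
  if (fmt == "IEEE_FLOAT_32") {
    raw <- readBin(con, numeric(), n = sz / 4, size = 4, endian = "little")
  } else {
    raw <- readBin(con, integer(), n = sz / 2, size = 2, endian = "little")
  }
  nsamp <- length(raw) %/% ns
  sig <- matrix(raw[seq_len(nsamp * ns)], nrow = ns) * res
  list(signal = sig, fs = fs, channel_names = labels)
}

read_matrix_sidecar <- function(path, sidecar) {
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$channel_names))
    stopf("sidecar '%s' lacks channel_names; a montage is required", sidecar)
  if (is.null(meta$fs))
    stopf("sidecar '%s' lacks the sampling rate fs", sidecar)
  m <- as.matrix(data.table::fread(path, header = FALSE))
  if (ncol(m) != length(meta$channel_names))
    stopf("matrix '%s' has %d columns but sidecar names %d channels",
          path, ncol(m), length(meta$channel_names))
  list(signal = t(m), fs = meta$fs, channel_names = meta$channel_names,
       meta = meta)
}

#' Read an EEG recording from disk
#'
#' Supports 16-bit EDF, BrainVision (`.vhdr` + multiplexed binary `.eeg`)
#' and a plain delimited samples-by-channels matrix with a JSON sidecar.
#' Cohort metadata (subject id, group) comes from explicit arguments, else
#' from a JSON sidecar at `<path>.json`.
#'
#' @param path file path (`.vhdr` for BrainVision, data file otherwise).
#' @param format `"edf"`, `"brainvision"` or `"matrix"`; guessed from the
#'   extension by default.
#' @param subject_id,group metadata overrides.
#' @param sidecar path to the JSON metadata sidecar (default
#'   `<path>.json` when present; required for `"matrix"`).
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path, format = c("auto", "edf", "brainvision",
                                            "matrix"),
                           subject_id = NULL, group = NULL, sidecar = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "edf", vhdr = "brainvision", "matrix")
  }
  sidecar <- sidecar %||%
    (if (file.exists(paste0(path, ".json"))) paste0(path, ".json"))
  meta <- if (!is.null(sidecar) && file.exists(sidecar))
    jsonlite::read_json(sidecar, simplifyVector = TRUE) else list()
  raw <- switch(format,
    edf = read_edf(path),
    brainvision = read_brainvision(path),
    matrix = {
      if (is.null(sidecar))
        stopf("matrix format needs a JSON sidecar with fs and channel_names")
      read_matrix_sidecar(path, sidecar)
    })
  new_recording(raw$signal, raw$fs, raw$channel_names,
                subject_id = subject_id %||% meta$subject_id %||%
                  raw$patient %||% "anon",
                group = group %||% meta$group %||% "HC")
}

#' Write / read feature tables
#'
#' Feature matrices are stored as delimited text with one row per epoch:
#' `subject_id`, `group`, `label`, then one `<band>_<channel>` column per
#' feature. The round trip is lossless to text precision (~15 significant
#' digits).
#'
#' @param fm an `eeg_features` object.
#' @param path output (input) file path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns the reconstructed `eeg_features`.
#' @export
write_feature_table <- function(fm, path) {
  stopifnot(inherits(fm, "eeg_features"))
  if (nrow(fm$values) > 0 && !all(is.finite(fm$values)))
    stopf("refusing to write %d non-finite feature cell(s)",
          sum(!is.finite(fm$values)))
  df <- data.table::data.table(subject_id = fm$subject_ids,
                               group = fm$groups, label = fm$labels)
  vals <- data.table::as.data.table(fm$values)
  data.table::setnames(vals, fm$feature_names)
  data.table::fwrite(cbind(df, vals), path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  feat_cols <- setdiff(names(dt), c("subject_id", "group", "label"))
  vals <- as.matrix(dt[, feat_cols, with = FALSE])
  if (nrow(dt) == 0) vals <- matrix(numeric(), 0, length(feat_cols))
  bands <- unique(sub("_.*$", "", feat_cols))
  new_features(vals, feature_names = feat_cols,
               labels = if (nrow(dt)) dt$label else integer(),
               subject_ids = if (nrow(dt)) dt$subject_id else character(),
               groups = if (nrow(dt)) dt$group else character(),
               layout = if (length(bands) > 1) "stacked" else "per_band",
               bands = bands,
               channels = unique(sub("^[^_]+_", "", feat_cols)))
}
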