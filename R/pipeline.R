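# End-to-end orchestration: simulate -> preprocess -> features -> train ->
# evaluate, with a single seed fanned out into stage substreams and a
# deterministic artifact tree.

#' Preprocess one recording into per-band epoch arrays
#'
#' The standard chain: crop to the analysis window, broadband band-pass
#' (0.5--50 Hz), optional ICA blink removal using Fp1/Fp2 as proxies, then
#' per-band filtering and segmentation into 1-s epochs. ICA runs once on
#' the broadband recording, before band decomposition, matching the
#' filtering -> artifact removal -> segmentation ordering of the reference
#' pipeline.
#'
#' @param rec an `eeg_recording`.
#' @param crop_s analysis window in seconds (defaults to the full length).
#' @param bands band table (default [eeg_bands()]).
#' @param broadband low/high edges of the broadband filter.
#' @param ica run ICA artifact removal (default TRUE).
#' @param ica_threshold proxy-correlation rejection threshold.
#' @param epoch_len_s,n_epochs segmentation parameters.
#' @param seed seed for the ICA start.
#' @return Named list of per-band `eeg_epochs`.
#' @export
preprocess_recording <- function(rec, crop_s = NULL, bands = eeg_bands(),
                                 broadband = c(0.5, 50), ica = TRUE,
                                 ica_threshold = 0.8, epoch_len_s = 1,
                                 n_epochs = NULL, seed = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.null(crop_s)) rec <- crop(rec, crop_s)
  rec <- bandpass(rec, broadband[1], broadband[2])
  if (ica)
    rec <- remove_artifacts_ica(rec, corr_threshold = ica_threshold,
                                seed = seed)$recording
  by_band <- decompose_bands(rec, bands)
  lapply(by_band, segment, epoch_len_s = epoch_len_s, n_epochs = n_epochs)
}

#' Per-band feature matrices for a whole cohort
#'
#' Runs [preprocess_recording()] on every recording and concatenates the
#' per-band epochs across the cohort before measuring Welch band powers.
#'
#' @param recordings list of `eeg_recording`.
#' @param crop_s,bands,ica,ica_threshold,n_epochs forwarded to
#'   [preprocess_recording()].
#' @param welch_window_frac Welch window length as a fraction of one
#'   epoch's samples (default 0.5).
#' @param welch_overlap overlap fraction (default 0.5).
#' @param seed base seed for per-recording ICA substreams.
#' @return Named list of `per_band` `eeg_features` spanning the cohort.
#' @export
cohort_band_features <- function(recordings, crop_s = NULL,
                                 bands = eeg_bands(), ica = FALSE,
                                 ica_threshold = 0.8, n_epochs = NULL,
                                 welch_window_frac = 0.5,
                                 welch_overlap = 0.5, seed = 1) {
  per_rec <- lapply(recordings, function(rec)
    preprocess_recording(rec, crop_s = crop_s, bands = bands, ica = ica,
                         ica_threshold = ica_threshold, n_epochs = n_epochs,
                         seed = substream_seed(seed, "ica", rec$subject_id,
                                               rec$group)))
  out <- lapply(seq_len(nrow(bands)), function(b) {
    ep <- bind_epochs(lapply(per_rec, `[[`, b))
    build_band_features(ep, bands[b, , drop = FALSE],
                        window_len = round(dim(ep$data)[3] *
                                             welch_window_frac),
                        overlap_frac = welch_overlap)
  })
  names(out) <- bands$name
  out
}

#' Fully-defaulted run configuration
#'
#' Every field has a default; the defaulted configuration runs the
#' synthetic `dataset1` / case 1 / 2D-CNN demonstration end to end.
#'
#' @param preset preset name (`"dataset1"` or `"dataset2"`).
#' @param case case id; must live on the chosen preset.
#' @param model `"svm"`, `"cnn2d"` or `"cnn1d"`.
#' @param band band for per-band models (`"svm"`, `"cnn1d"`).
#' @param cv `"dependent"` or `"independent"`.
#' @param folds fold count.
#' @param seed master seed fanned out to simulation, ICA, folds, training.
#' @param ica run ICA artifact removal during preprocessing.
#' @param duration_s,n_epochs optional scaled-down recording length and
#'   epoch count for quick runs (defaults: the preset values).
#' @param n_pd,n_hc cohort sizes (defaults: preset cohort).
#' @param synth overrides passed to [synth_config()] (named list).
#' @param cnn overrides passed to [train_config()] (named list).
#' @param out output directory for artifacts (`NULL` disables writing).
#' @return A `run_config` list.
#' @export
run_config <- function(preset = "dataset1", case = "case1", model = "cnn2d",
                       band = "gamma", cv = "dependent", folds = 5,
                       seed = 42, ica = TRUE, duration_s = NULL,
                       n_epochs = NULL, n_pd = NULL, n_hc = NULL,
                       synth = list(), cnn = list(), out = NULL) {
  cs <- case_spec(case)
  if (cs$preset != preset)
    stopf("%s is defined on %s, not %s", case, cs$preset, preset)
  structure(list(preset = preset, case = case, model = model, band = band,
                 cv = cv, folds = folds, seed = as.integer(seed), ica = ica,
                 duration_s = duration_s, n_epochs = n_epochs,
                 n_pd = n_pd, n_hc = n_hc, synth = synth, cnn = cnn,
                 out = out),
            class = "run_config")
}

#' Run the synthetic end-to-end pipeline
#'
#' Simulates a cohort, preprocesses it, builds band-power features,
#' restricts them to the configured case and evaluates the configured
#' classifier under cross-validation. With `cfg$out` set, writes a
#' deterministic artifact tree: the feature table, the evaluation report
#' (JSON) and a manifest carrying the configuration, its hash and the
#' package version. Reports contain no timestamps, so reruns are
#' byte-identical.
#'
#' @param cfg a [run_config()].
#' @return A list: `cv` (the `eeg_cv` report), `features` (the case
#'   feature matrix used), and `paths` of artifacts when written.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  preset <- dataset_preset(cfg$preset)
  sargs <- c(list(preset = preset, seed = substream_seed(cfg$seed, "sim"),
                  n_pd = cfg$n_pd, n_hc = cfg$n_hc,
                  duration_s = cfg$duration_s),
             cfg$synth)
  scfg <- do.call(synth_config, sargs[!vapply(sargs, is.null, TRUE)])
  message(sprintf("[simulate] %s: %d PD + %d HC subjects",
                  preset$name, scfg$n_pd, scfg$n_hc))
  recs <- simulate_cohort(scfg)
  recs <- make_case(recs, case_spec(cfg$case))
  message(sprintf("[preprocess] %d recordings, ica=%s",
                  length(recs), cfg$ica))
  n_epochs <- cfg$n_epochs %||%
    (if (is.null(cfg$duration_s)) preset$n_epochs else NULL)
  per_band <- cohort_band_features(recs, ica = cfg$ica,
                                   n_epochs = n_epochs,
                                   seed = substream_seed(cfg$seed, "ica"))
  fm <- if (cfg$model %in% c("svm", "cnn1d")) per_band[[cfg$band]]
        else stack_bands(per_band)
  message(sprintf("[features] %d epochs x %d features (%s)",
                  nrow(fm$values), ncol(fm$values), fm$layout))
  cnn_cfg <- do.call(train_config, cfg$cnn)
  cv <- evaluate_model(fm, model = cfg$model, scheme = cfg$cv,
                       k = cfg$folds, seed = substream_seed(cfg$seed, "cv"),
                       cnn_config = cnn_cfg)
  message(sprintf("[evaluate] %s %s-CV mean accuracy %.4f",
                  cfg$model, cfg$cv, cv$summary["accuracy"]))
  paths <- NULL
  if (!is.null(cfg$out)) paths <- write_run_artifacts(cfg, fm, cv)
  list(cv = cv, features = fm, paths = paths)
}

write_run_artifacts <- function(cfg, fm, cv) {
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  feat_path <- file.path(cfg$out, "features.csv")
  write_feature_table(fm, feat_path)
  report <- list(
    model = cv$model,
    folds = lapply(cv$folds, function(f)
      list(confusion = as.list(f$confusion),
           metrics = as.list(f$metrics), n = f$n)),
    summary = as.list(cv$summary)
  )
  report_path <- file.path(cfg$out, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  cfg_path <- file.path(cfg$out, "config.json")
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE,
                       null = "null")
  manifest <- list(
    package = "pdeeg",
    version = as.character(utils::packageVersion("pdeeg")),
    seed = cfg$seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    artifacts = c("features.csv", "report.json", "config.json")
  )
  manifest_path <- file.path(cfg$out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  c(features = feat_path, report = report_path, config = cfg_path,
    manifest = manifest_path)
}
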