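# Case construction, cross-validation schemes, metrics and the ablation
# harness.

#' Classification case definitions
#'
#' Three binary contrasts: `case1` = medicated patients (PD_ON) vs controls
#' and `case2` = unmedicated patients (PD_OFF) vs controls, both on the
#' `dataset1` geometry; `case3` = patients (any medication state) vs
#' controls on `dataset2`.
#'
#' @param id `"case1"`, `"case2"` or `"case3"`.
#' @return A `case_spec` list with `id`, `positive`, `negative` group sets
#'   and the associated `preset` name.
#' @export
case_spec <- function(id = c("case1", "case2", "case3")) {
  id <- match.arg(id)
  out <- switch(id,
    case1 = list(id = id, positive = "PD_ON", negative = "HC",
                 preset = "dataset1"),
    case2 = list(id = id, positive = "PD_OFF", negative = "HC",
                 preset = "dataset1"),
    case3 = list(id = id, positive = c("PD", "PD_OFF", "PD_ON"),
                 negative = "HC", preset = "dataset2"))
  structure(out, class = "case_spec")
}

#' Subset epochs or features to a classification case
#'
#' Keeps only rows whose cohort group belongs to the case's positive or
#' negative set and assigns binary labels (negative set 0, positive set 1).
#' Works on `eeg_epochs`, `eeg_features` or a list of recordings.
#'
#' @param x an `eeg_epochs`, `eeg_features`, or list of `eeg_recording`.
#' @param case a [case_spec()].
#' @return The filtered object of the same class.
#' @export
make_case <- function(x, case) {
  stopifnot(inherits(case, "case_spec"))
  groups_of <- function(g) {
    keep <- g %in% c(case$positive, case$negative)
    if (!any(g[keep] %in% case$positive) || !any(g[keep] %in% case$negative))
      stopf("%s has zero members of one class (groups present: %s)",
            case$id, paste(unique(g), collapse = ", "))
    keep
  }
  if (inherits(x, "eeg_epochs")) {
    keep <- groups_of(x$groups)
    new_epochs(x$data[keep, , , drop = FALSE], x$fs, x$epoch_len_s,
               x$channel_names,
               labels = as.integer(x$groups[keep] %in% case$positive),
               subject_ids = x$subject_ids[keep], groups = x$groups[keep])
  } else if (inherits(x, "eeg_features")) {
    keep <- groups_of(x$groups)
    new_features(x$values[keep, , drop = FALSE], x$feature_names,
                 labels = as.integer(x$groups[keep] %in% case$positive),
                 subject_ids = x$subject_ids[keep], groups = x$groups[keep],
                 layout = x$layout, bands = x$bands, channels = x$channels,
                 standardized = x$standardized)
  } else if (is.list(x)) {
    g <- vapply(x, `[[`, "", "group")
    keep <- groups_of(g)
    x[keep]
  } else stopf("make_case expects epochs, features or a recording list")
}

# Stratified assignment of indices to k folds, deterministic under seed.
stratified_folds <- function(labels, k, seed) {
  folds <- vector("list", k)
  with_seed(seed, {
    for (cls in unique(labels)) {
      ix <- sample(which(labels == cls))
      cut_id <- rep_len(seq_len(k), length(ix))
      for (f in seq_len(k))
        folds[[f]] <- c(folds[[f]], ix[cut_id == f])
    }
  })
  lapply(folds, sort)
}

#' Single stratified train/test holdout split
#'
#' Epoch-level stratified random split (default 9:1).
#'
#' @param fm an `eeg_features`.
#' @param test_frac held-out fraction in (0, 1).
#' @param seed split seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_holdout <- function(fm, test_frac = 0.1, seed = 42) {
  stopifnot(inherits(fm, "eeg_features"), test_frac > 0, test_frac < 1)
  n <- nrow(fm$values)
  test <- with_seed(seed, {
    unlist(lapply(split(seq_len(n), fm$labels), function(ix)
      sample(ix, round(length(ix) * test_frac))))
  })
  test <- sort(test)
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Subject-dependent (epoch-level) k-fold split
#'
#' Stratified folds over epochs; a subject's epochs may land in both the
#' training and the test side of a fold, which is what makes the scheme
#' subject-dependent.
#'
#' @param fm an `eeg_features`.
#' @param k number of folds (>= 2).
#' @param seed fold-assignment seed (default 42).
#' @return List of k integer vectors of test-epoch indices (a partition).
#' @export
split_subject_dependent <- function(fm, k = 5, seed = 42) {
  stopifnot(inherits(fm, "eeg_features"), k >= 2)
  n <- nrow(fm$values)
  if (k > n) stopf("k = %d exceeds the %d epochs", k, n)
  stratified_folds(fm$labels, k, seed)
}

#' Subject-independent (grouped) cross-validation split
#'
#' Folds are formed over subjects, so no subject's epochs ever cross the
#' train/test boundary; both sessions of a dual-session patient travel
#' together because they share the subject id. The default (`k = NULL`) is
#' leave-one-subject-out.
#'
#' @param fm an `eeg_features`.
#' @param k number of subject folds, or `NULL` for leave-one-subject-out.
#' @param seed fold-assignment seed (ignored for leave-one-subject-out).
#' @return List of integer vectors of test-epoch indices.
#' @export
split_subject_independent <- function(fm, k = NULL, seed = 42) {
  stopifnot(inherits(fm, "eeg_features"))
  subj <- fm$subject_ids
  usubj <- unique(subj)
  subj_label <- vapply(usubj, function(s)
    max(fm$labels[subj == s]), 0L)
  if (length(unique(subj_label)) < 2 || min(table(subj_label)) < 2)
    stopf("subject-independent CV needs >= 2 subjects per class")
  if (is.null(k)) {
    folds <- lapply(usubj, function(s) which(subj == s))
  } else {
    sf <- stratified_folds(subj_label, k, seed)
    folds <- lapply(sf, function(si) which(subj %in% usubj[si]))
  }
  # every fold's training side must retain both classes
  for (f in seq_along(folds)) {
    tr <- fm$labels[-folds[[f]]]
    if (length(unique(tr)) < 2)
      stopf("fold %d would leave a single-class training set", f)
  }
  folds
}

#' Confusion matrix, scalar metrics, ROC and AUC
#'
#' Counts are tallied directly from the label vectors; sensitivity is
#' TP/(TP+FN), specificity TN/(TN+FP), precision TP/(TP+FP), F1 the
#' harmonic mean of precision and sensitivity. When scores are supplied the
#' ROC is swept over the unique score values and the AUC integrated by the
#' trapezoidal rule; with a single-class truth the AUC is reported as `NA`.
#'
#' @param y_true,y_pred 0/1 vectors of equal length.
#' @param y_score optional continuous scores for ROC/AUC.
#' @return An `eeg_eval` list: `confusion` (tn, fp, fn, tp), `metrics`
#'   (accuracy, sensitivity, specificity, precision, f1, auc), and `roc`
#'   (data.frame of fpr/tpr points, score-descending) when scores are given.
#' @export
compute_metrics <- function(y_true, y_pred, y_score = NULL) {
  stopifnot(length(y_true) == length(y_pred))
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  tp <- sum(y_true == 1 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  div <- function(a, b) if (b > 0) a / b else NA_real_
  sens <- div(tp, tp + fn); spec <- div(tn, tn + fp)
  prec <- div(tp, tp + fp)
  f1 <- if (!is.na(prec) && !is.na(sens) && (prec + sens) > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  roc <- NULL; auc <- NA_real_
  if (!is.null(y_score) && length(unique(y_true)) == 2) {
    stopifnot(length(y_score) == length(y_true))
    thr <- c(Inf, sort(unique(y_score), decreasing = TRUE))
    np <- sum(y_true == 1); nn <- sum(y_true == 0)
    tpr <- fpr <- numeric(length(thr))
    for (i in seq_along(thr)) {
      pred <- y_score >= thr[i]
      tpr[i] <- sum(pred & y_true == 1) / np
      fpr[i] <- sum(pred & y_true == 0) / nn
    }
    roc <- data.frame(threshold = thr, fpr = fpr, tpr = tpr)
    auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  }
  structure(list(
    confusion = c(tn = tn, fp = fp, fn = fn, tp = tp),
    metrics = c(accuracy = (tp + tn) / length(y_true),
                sensitivity = sens, specificity = spec,
                precision = prec, f1 = f1, auc = auc),
    roc = roc, n = length(y_true)
  ), class = "eeg_eval")
}

#' @export
print.eeg_eval <- function(x, ...) {
  cat(sprintf("<eeg_eval> n=%d acc=%.4f sens=%.4f spec=%.4f auc=%s\n",
              x$n, x$metrics["accuracy"], x$metrics["sensitivity"],
              x$metrics["specificity"],
              ifelse(is.na(x$metrics["auc"]), "NA",
                     sprintf("%.4f", x$metrics["auc"]))))
  invisible(x)
}

# Train/evaluate one model family over a list of test folds. The scaler is
# refitted on each fold's training rows only. Returns per-fold eeg_eval
# objects plus unweighted fold-mean metrics.
crossval_model <- function(fm, folds, model = c("svm", "cnn2d", "cnn1d"),
                           seed = 42, cnn_config = NULL, svm_C = 1) {
  model <- match.arg(model)
  per_fold <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    te <- folds[[f]]
    tr <- setdiff(seq_len(nrow(fm$values)), te)
    # subject leak check for grouped schemes is re-done on every run
    fm_tr <- subset_features(fm, tr)
    fm_te <- subset_features(fm, te)
    sc <- suppressWarnings(fit_standardizer(fm_tr))
    fm_tr <- apply_standardizer(sc, fm_tr)
    fm_te <- apply_standardizer(sc, fm_te)
    fold_seed <- substream_seed(seed, "fold", f)
    handle <- if (model == "svm") {
      train_svm_linear(fm_tr, seed = fold_seed, C = svm_C)
    } else {
      spec <- if (model == "cnn2d")
        build_cnn2d(length(fm$bands), length(fm$channels))
      else build_cnn1d(fm$bands, length(fm$channels))
      cfg <- cnn_config %||% train_config()
      cfg$seed <- fold_seed
      train_cnn(spec, fm_tr, cfg = cfg)
    }
    pred <- predict(handle, fm_te)
    per_fold[[f]] <- compute_metrics(fm_te$labels, pred$label, pred$score)
  }
  mm <- do.call(rbind, lapply(per_fold, `[[`, "metrics"))
  structure(list(model = model, folds = per_fold,
                 fold_metrics = mm,
                 summary = colMeans(mm, na.rm = TRUE)),
            class = "eeg_cv")
}

#' @export
print.eeg_cv <- function(x, ...) {
  cat(sprintf("<eeg_cv %s> %d folds: mean acc=%.4f sens=%.4f spec=%.4f auc=%.4f\n",
              x$model, length(x$folds), x$summary["accuracy"],
              x$summary["sensitivity"], x$summary["specificity"],
              x$summary["auc"]))
  invisible(x)
}

# Row subset of a feature matrix, metadata included.
subset_features <- function(fm, ix) {
  new_features(fm$values[ix, , drop = FALSE], fm$feature_names,
               labels = fm$labels[ix], subject_ids = fm$subject_ids[ix],
               groups = fm$groups[ix], layout = fm$layout, bands = fm$bands,
               channels = fm$channels, standardized = fm$standardized)
}

#' Cross-validated evaluation of one classifier
#'
#' Builds the requested fold scheme, refits the standardizer inside every
#' fold, trains the model and aggregates per-fold metrics. Subject folds
#' are checked for leakage on every run.
#'
#' @param fm an (unstandardized) `eeg_features` with labels and subjects.
#' @param model `"svm"`, `"cnn2d"` or `"cnn1d"`.
#' @param scheme `"dependent"` (epoch-level stratified folds) or
#'   `"independent"` (grouped by subject).
#' @param k folds (default 5; `NULL` with `"independent"` gives
#'   leave-one-subject-out).
#' @param seed controls fold assignment and per-fold training seeds.
#' @param cnn_config optional [train_config()] for the CNN models.
#' @param svm_C SVM penalty.
#' @return An `eeg_cv` object with per-fold reports and fold-mean metrics.
#' @export
evaluate_model <- function(fm, model = c("svm", "cnn2d", "cnn1d"),
                           scheme = c("dependent", "independent"), k = 5,
                           seed = 42, cnn_config = NULL, svm_C = 1) {
  model <- match.arg(model); scheme <- match.arg(scheme)
  folds <- if (scheme == "dependent")
    split_subject_dependent(fm, k = k %||% 5, seed = seed)
  else split_subject_independent(fm, k = k, seed = seed)
  if (scheme == "independent") {
    for (f in seq_along(folds)) {
      leak <- intersect(unique(fm$subject_ids[folds[[f]]]),
                        unique(fm$subject_ids[-folds[[f]]]))
      if (length(leak))
        stopf("subject leakage across fold %d: %s", f,
              paste(leak, collapse = ", "))
    }
  }
  crossval_model(fm, folds, model, seed = seed, cnn_config = cnn_config,
                 svm_C = svm_C)
}

#' Per-band 1D-CNN vs band-stacked 2D-CNN ablation
#'
#' Trains the per-band 1D models and the stacked 2D model under
#' subject-dependent cross-validation and tabulates fold-mean metrics.
#'
#' @param per_band named list of `per_band` `eeg_features` (all five bands).
#' @param bands bands to ablate (default: all in `per_band`).
#' @param k,seed cross-validation folds and seed.
#' @param cnn_config optional [train_config()].
#' @return data.frame with one row per (model, band) and the fold-mean
#'   metrics.
#' @export
run_ablation <- function(per_band, bands = names(per_band), k = 5, seed = 42,
                         cnn_config = NULL) {
  rows <- list()
  for (b in bands) {
    cv <- evaluate_model(per_band[[b]], "cnn1d", "dependent", k = k,
                         seed = seed, cnn_config = cnn_config)
    rows[[length(rows) + 1]] <-
      data.frame(model = "cnn1d", band = b, t(cv$summary))
  }
  stacked <- stack_bands(per_band)
  cv <- evaluate_model(stacked, "cnn2d", "dependent", k = k, seed = seed,
                       cnn_config = cnn_config)
  rows[[length(rows) + 1]] <-
    data.frame(model = "cnn2d", band = "all", t(cv$summary))
  do.call(rbind, rows)
}
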