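# Linear maximum-margin baseline classifier.
#
# L2-regularised hinge-loss SVM solved by dual coordinate descent
# (liblinear's algorithm for L1-loss SVC); the bias is handled by an
# appended constant column. Decision scores w.x + b are exposed for ROC
# analysis; hard labels threshold the score at 0, equivalently the
# calibrated probability surrogate at 0.5.

#' Train a linear SVM on one band's standardized features
#'
#' @param fm a standardized `per_band` `eeg_features` (or any standardized
#'   feature matrix).
#' @param labels optional 0/1 labels (default `fm$labels`).
#' @param C hinge-loss penalty (default 1).
#' @param max_pass,tol optimiser budget and projected-gradient tolerance.
#' @param seed seed for the (single, deterministic) row shuffle that
#'   precedes coordinate descent.
#' @return An `eeg_classifier` handle with `kind = "svm_linear"`.
#' @export
train_svm_linear <- function(fm, labels = NULL, C = 1, max_pass = 1000,
                             tol = 1e-4, seed = 1) {
  stopifnot(inherits(fm, "eeg_features"))
  labels <- as.integer(labels %||% fm$labels)
  if (length(unique(labels)) < 2)
    stopf("training labels contain a single class")
  if (!fm$standardized)
    warning("features do not look standardized; fit a scaler on the ",
            "training rows first", call. = FALSE)
  X <- cbind(fm$values, 1)                  # bias column
  y <- ifelse(labels == 1, 1, -1)
  ord <- with_seed(seed, sample.int(nrow(X)))
  fit <- svm_dcd_cpp(X[ord, , drop = FALSE], y[ord], C,
                     as.integer(max_pass), tol)
  structure(list(kind = "svm_linear",
                 w = fit$w[-length(fit$w)], b = fit$w[length(fit$w)],
                 C = C, converged = fit$converged,
                 feature_names = fm$feature_names, layout = fm$layout,
                 bands = fm$bands, channels = fm$channels),
            class = "eeg_classifier")
}

#' @export
print.eeg_classifier <- function(x, ...) {
  cat(sprintf("<eeg_classifier %s> %d features (%s)\n", x$kind,
              length(x$feature_names %||% character()),
              paste(x$bands, collapse = "+")))
  invisible(x)
}

# Raw decision scores (margins) of a linear SVM.
svm_decision <- function(handle, fm) {
  drop(fm$values %*% handle$w + handle$b)
}

#' Predict epoch classes
#'
#' Uniform prediction contract for every classifier kind: per-epoch scores
#' (probabilities for the CNNs, logistic-squashed margins for the SVM so
#' they live in `[0, 1]`), and hard labels at the 0.5 threshold with ties
#' assigned to the positive class.
#'
#' @param object an `eeg_classifier`.
#' @param fm an `eeg_features` whose layout and columns match the fit.
#' @param ... unused.
#' @return A list with `prob`, `score` and `label` vectors.
#' @export
predict.eeg_classifier <- function(object, fm, ...) {
  stopifnot(inherits(fm, "eeg_features"))
  if (!identical(object$feature_names, fm$feature_names))
    stopf("layout mismatch: model fitted on %d features (%s ...), given %d (%s ...)",
          length(object$feature_names),
          paste(head(object$feature_names, 2), collapse = ", "),
          length(fm$feature_names),
          paste(head(fm$feature_names, 2), collapse = ", "))
  if (object$kind == "svm_linear") {
    score <- svm_decision(object, fm)
    prob <- 1 / (1 + exp(-score))
  } else {
    prob <- cnn_forward_prob(object, fm)
    score <- prob
  }
  list(prob = prob, score = score, label = as.integer(prob >= 0.5))
}
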