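# ICA-based removal of ocular artifacts.
#
# FastICA with the tanh contrast and symmetric decorrelation, run on the
# broadband-filtered recording with as many components as channels.
# Components whose time courses correlate strongly with either frontopolar
# proxy channel (Fp1/Fp2) are zeroed before reconstruction.

# Symmetric FastICA on a channels x samples matrix. Returns the unmixing
# applied to whitened data plus everything needed to reconstruct.
fastica_fit <- function(X, seed = 1, max_iter = 300, tol = 1e-4) {
  C <- nrow(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  n <- ncol(Xc)
  cov <- tcrossprod(Xc) / n
  eg <- eigen(cov, symmetric = TRUE)
  keep <- eg$values > max(eg$values) * 1e-12
  D <- eg$values[keep]; E <- eg$vectors[, keep, drop = FALSE]
  K <- diag(1 / sqrt(D), nrow = length(D)) %*% t(E)   # whitening (k x C)
  Z <- K %*% Xc                                       # whitened sources
  k <- nrow(Z)
  sym_decorrelate <- function(W) {
    s <- eigen(W %*% t(W), symmetric = TRUE)
    s$vectors %*% diag(1 / sqrt(pmax(s$values, 1e-300)), k) %*%
      t(s$vectors) %*% W
  }
  W <- with_seed(seed, matrix(rnorm(k * k), k, k))
  W <- sym_decorrelate(W)
  converged <- FALSE
  # Convergence is declared either on the usual unmixing-matrix criterion
  # or when the tanh contrast objective stalls: with (near-)Gaussian
  # background sources the Gaussian subspace is rotationally degenerate, so
  # W itself never settles even though every identifiable (non-Gaussian)
  # component has.
  gauss_ref <- 0.3745096           # E[log cosh Z] for standard normal Z
  obj_prev <- Inf
  stall <- 0L
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    W_new <- (G %*% t(Z)) / n - diag(rowMeans(1 - G^2), k) %*% W
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(abs(diag(W_new %*% t(W))) - 1))
    W <- W_new
    if (delta < tol) { converged <- TRUE; break }
    obj <- sum((rowMeans(log(cosh(W %*% Z))) - gauss_ref)^2)
    stall <- if (it >= 30 &&
                 abs(obj - obj_prev) / max(obj, 1e-3) < 1e-2) stall + 1L
             else 0L
    obj_prev <- obj
    if (stall >= 5L) { converged <- TRUE; break }
  }
  # sources S = W Z; reconstruction X = A S + mu with A = pinv(W K)
  A <- E %*% diag(sqrt(D), length(D)) %*% t(W)        # C x k mixing
  list(W = W, K = K, A = A, mu = mu, S = W %*% Z, converged = converged)
}

#' Remove blink artifacts with ICA
#'
#' Decomposes the recording into independent components (one per channel),
#' flags components whose absolute Pearson correlation with either proxy
#' channel's raw time course reaches `corr_threshold`, zeroes the flagged
#' components and reconstructs the signal. Run this on the broadband
#' (0.5--50 Hz) recording, before band decomposition and segmentation.
#'
#' If FastICA fails to converge the decomposition is retried once from a
#' different deterministic start before erroring.
#'
#' @param rec a broadband-filtered `eeg_recording`.
#' @param proxy_channels ocular proxy channels (default Fp1 and Fp2).
#' @param corr_threshold absolute-correlation rejection threshold in (0, 1];
#'   default 0.8. Values above 1 reject nothing and return the (numerically
#'   reconstructed) input.
#' @param seed integer seed for the FastICA start.
#' @return A list: `recording` (cleaned) and `report`, a data.frame with the
#'   flagged `component` indices, the proxy `channel` and the `correlation`.
#' @export
remove_artifacts_ica <- function(rec, proxy_channels = c("Fp1", "Fp2"),
                                 corr_threshold = 0.8, seed = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  idx <- vapply(proxy_channels, function(p) channel_index(rec, p), 0L)
  if (anyNA(idx))
    stopf("proxy channel(s) absent from montage: %s",
          paste(proxy_channels[is.na(idx)], collapse = ", "))
  fit <- fastica_fit(rec$signal, seed = substream_seed(seed, "ica"))
  if (!fit$converged)
    fit <- fastica_fit(rec$signal, seed = substream_seed(seed, "ica-retry"))
  if (!fit$converged)
    stopf("FastICA failed to converge twice; inspect the recording")
  S <- fit$S
  prox <- rec$signal[idx, , drop = FALSE]
  cors <- abs(stats::cor(t(S), t(prox)))          # components x proxies
  hit <- which(cors >= corr_threshold, arr.ind = TRUE)
  report <- data.frame(
    component = hit[, 1],
    channel = proxy_channels[hit[, 2]],
    correlation = cors[hit],
    stringsAsFactors = FALSE
  )
  rejected <- unique(report$component)
  S_clean <- S
  if (length(rejected)) S_clean[rejected, ] <- 0
  out <- rec
  out$signal <- fit$A %*% S_clean + fit$mu
  rownames(out$signal) <- rec$channel_names
  list(recording = out, report = report)
}
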