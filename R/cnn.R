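# Compact convolutional classifiers over bands x channels PSD maps.
#
# Architecture (2D): two 3x3 same-padding convolutions with ReLU, each
# followed by a 2x1 max-pool along the channel axis (halving it, floor for
# odd sizes), a ReLU fully-connected layer and a single sigmoid output.
# The 1D ablation variant applies the same depth/pooling scheme to one
# band's channel vector (3x1 kernels, 2x1 pools). Layers are realised as
# im2col + BLAS matrix products with hand-written backpropagation and Adam;
# everything is seeded and deterministic on one device.
#
# Input maps are oriented channels x bands, so the 2x1 pools act on the
# channel axis: 32 channels pool 32 -> 16 -> 8 over the two blocks.

conv_im2col <- function(A, kh, kw) {
  d <- dim(A); N <- d[1]; H <- d[2]; W <- d[3]; Ci <- d[4]
  ph <- (kh - 1) %/% 2; pw <- (kw - 1) %/% 2
  P <- array(0, c(N, H + 2 * ph, W + 2 * pw, Ci))
  P[, ph + seq_len(H), pw + seq_len(W), ] <- A
  cols <- matrix(0, N * H * W, kh * kw * Ci)
  k <- 0L
  for (ci in seq_len(Ci)) for (dj in seq_len(kw)) for (di in seq_len(kh)) {
    k <- k + 1L
    cols[, k] <- as.vector(P[, di + seq_len(H) - 1, dj + seq_len(W) - 1, ci])
  }
  cols
}

conv_col2im <- function(dcols, N, H, W, Ci, kh, kw) {
  ph <- (kh - 1) %/% 2; pw <- (kw - 1) %/% 2
  dP <- array(0, c(N, H + 2 * ph, W + 2 * pw, Ci))
  k <- 0L
  for (ci in seq_len(Ci)) for (dj in seq_len(kw)) for (di in seq_len(kh)) {
    k <- k + 1L
    hi <- di + seq_len(H) - 1; wi <- dj + seq_len(W) - 1
    dP[, hi, wi, ci] <-
      array(dP[, hi, wi, ci, drop = FALSE], c(N, H, W)) +
      array(dcols[, k], c(N, H, W))
  }
  dP[, ph + seq_len(H), pw + seq_len(W), , drop = FALSE]
}

conv_forward <- function(A, Wmat, bias, kh, kw) {
  d <- dim(A)
  cols <- conv_im2col(A, kh, kw)
  Z <- sweep(cols %*% Wmat, 2, bias, "+")
  list(out = array(Z, c(d[1], d[2], d[3], length(bias))), cols = cols)
}

conv_backward <- function(dOut, cache_cols, Wmat, dims_in, kh, kw) {
  d <- dim(dOut)
  dZ <- matrix(dOut, nrow = d[1] * d[2] * d[3])
  list(dW = crossprod(cache_cols, dZ),
       db = colSums(dZ),
       dA = conv_col2im(dZ %*% t(Wmat), dims_in[1], dims_in[2], dims_in[3],
                        dims_in[4], kh, kw))
}

pool_forward <- function(A) {
  d <- dim(A); Hp <- d[2] %/% 2
  i1 <- seq(1, by = 2, length.out = Hp)
  a <- A[, i1, , , drop = FALSE]
  b <- A[, i1 + 1, , , drop = FALSE]
  mask <- a >= b                       # ties keep the earlier row
  list(out = pmax(a, b), mask = mask, H_in = d[2])
}

pool_backward <- function(dOut, cache) {
  d <- dim(dOut)
  dA <- array(0, c(d[1], cache$H_in, d[3], d[4]))
  i1 <- seq(1, by = 2, length.out = d[2])
  da <- dOut; da[!cache$mask] <- 0
  db <- dOut; db[cache$mask] <- 0
  dA[, i1, , ] <- da
  dA[, i1 + 1, , ] <- db
  dA
}

cnn_pooled_height <- function(h) (h %/% 2) %/% 2

#' Specify the band-stacked 2D CNN
#'
#' Two 3x3 same-padding convolutions (ReLU), each followed by a 2x1
#' max-pool along the channel axis, one ReLU fully-connected layer and a
#' sigmoid output. For a 5 x 32 bands-by-channels map the channel axis
#' pools 32 -> 16 -> 8.
#'
#' @param n_bands number of stacked bands (rows of the input map).
#' @param n_channels number of channels (pooled axis); at least 4 so both
#'   pools have something to halve.
#' @param conv_filters filter counts for the two blocks (default 16, 32).
#' @param fc_units width of the fully-connected layer (default 64).
#' @return A `cnn_spec` list.
#' @export
build_cnn2d <- function(n_bands = 5, n_channels, conv_filters = c(16L, 32L),
                        fc_units = 64L) {
  if (n_channels < 4)
    stopf("n_channels must be >= 4 for two 2x1 pools (got %d)", n_channels)
  structure(list(kind = "cnn2d", input_map = c(n_bands, n_channels),
                 H = as.integer(n_channels), W = as.integer(n_bands),
                 kh = 3L, kw = 3L,
                 conv_filters = as.integer(conv_filters),
                 fc_units = as.integer(fc_units)),
            class = "cnn_spec")
}

#' Specify the per-band 1D CNN ablation model
#'
#' Same depth and pooling scheme as [build_cnn2d()] applied to a single
#' band's channel vector: 3x1 kernels, 2x1 pools (32 -> 16 -> 8).
#'
#' @param band band name the model is meant for (recorded on the handle).
#' @param n_channels channels per band; at least 4.
#' @inheritParams build_cnn2d
#' @return A `cnn_spec` list.
#' @export
build_cnn1d <- function(band, n_channels, conv_filters = c(16L, 32L),
                        fc_units = 64L) {
  if (n_channels < 4)
    stopf("n_channels must be >= 4 for two 2x1 pools (got %d)", n_channels)
  structure(list(kind = "cnn1d", band = band,
                 input_map = c(1L, n_channels),
                 H = as.integer(n_channels), W = 1L, kh = 3L, kw = 1L,
                 conv_filters = as.integer(conv_filters),
                 fc_units = as.integer(fc_units)),
            class = "cnn_spec")
}

#' Training configuration for the CNNs
#'
#' @param learning_rate Adam step size (default 1e-3).
#' @param epochs maximum training epochs (default 30).
#' @param batch_size minibatch size (default 32).
#' @param validation_frac fraction of the training rows held out for early
#'   stopping (default 0.1; 0 disables early stopping).
#' @param patience early-stopping patience on validation loss (default 5).
#' @param seed seed controlling initialisation, the validation split and
#'   minibatch shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, epochs = 30L, batch_size = 32L,
                         validation_frac = 0.1, patience = 5L, seed = 42L) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            validation_frac >= 0, validation_frac < 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 validation_frac = validation_frac,
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "train_config")
}

cnn_init_params <- function(spec, seed) {
  f1 <- spec$conv_filters[1]; f2 <- spec$conv_filters[2]
  k1 <- spec$kh * spec$kw              # single input channel
  k2 <- spec$kh * spec$kw * f1
  hp <- cnn_pooled_height(spec$H)
  nflat <- hp * spec$W * f2
  with_seed(seed, list(
    W1 = matrix(rnorm(k1 * f1, 0, sqrt(2 / k1)), k1, f1),
    b1 = numeric(f1),
    W2 = matrix(rnorm(k2 * f2, 0, sqrt(2 / k2)), k2, f2),
    b2 = numeric(f2),
    W3 = matrix(rnorm(nflat * spec$fc_units, 0, sqrt(2 / nflat)),
                nflat, spec$fc_units),
    b3 = numeric(spec$fc_units),
    W4 = matrix(rnorm(spec$fc_units, 0, sqrt(1 / spec$fc_units)),
                spec$fc_units, 1),
    b4 = 0
  ))
}

# Forward pass; returns probabilities plus caches when `train = TRUE`.
cnn_forward <- function(spec, par, X, train = FALSE) {
  d <- dim(X)
  A0 <- array(X, c(d[1], d[2], d[3], 1))
  c1 <- conv_forward(A0, par$W1, par$b1, spec$kh, spec$kw)
  a1 <- pmax(c1$out, 0)
  p1 <- pool_forward(a1)
  c2 <- conv_forward(p1$out, par$W2, par$b2, spec$kh, spec$kw)
  a2 <- pmax(c2$out, 0)
  p2 <- pool_forward(a2)
  dp2 <- dim(p2$out)
  flat <- matrix(p2$out, nrow = d[1])
  z3 <- sweep(flat %*% par$W3, 2, par$b3, "+")
  a3 <- pmax(z3, 0)
  z4 <- drop(a3 %*% par$W4) + par$b4
  prob <- 1 / (1 + exp(-z4))
  if (!train) return(list(prob = prob))
  list(prob = prob, A0 = A0, c1 = c1, a1 = a1, p1 = p1, c2 = c2, a2 = a2,
       p2 = p2, flat = flat, a3 = a3, dims = list(d0 = dim(A0),
                                                  d1 = dim(p1$out),
                                                  dp2 = dp2))
}

cnn_backward <- function(spec, par, fw, y) {
  N <- length(y)
  dz4 <- matrix((fw$prob - y) / N, ncol = 1)
  g <- list()
  g$W4 <- crossprod(fw$a3, dz4)
  g$b4 <- sum(dz4)
  da3 <- dz4 %*% t(par$W4)
  dz3 <- da3 * (fw$a3 > 0)
  g$W3 <- crossprod(fw$flat, dz3)
  g$b3 <- colSums(dz3)
  dflat <- dz3 %*% t(par$W3)
  dp2 <- array(dflat, fw$dims$dp2)
  da2 <- pool_backward(dp2, fw$p2)
  dz2 <- da2 * (fw$a2 > 0)
  bk2 <- conv_backward(dz2, fw$c2$cols, par$W2, fw$dims$d1, spec$kh, spec$kw)
  g$W2 <- bk2$dW; g$b2 <- bk2$db
  da1 <- pool_backward(bk2$dA, fw$p1)
  dz1 <- da1 * (fw$a1 > 0)
  bk1 <- conv_backward(dz1, fw$c1$cols, par$W1, fw$dims$d0, spec$kh, spec$kw)
  g$W1 <- bk1$dW; g$b1 <- bk1$db
  g
}

bce_loss <- function(prob, y) {
  eps <- 1e-12
  -mean(y * log(prob + eps) + (1 - y) * log(1 - prob + eps))
}

# Reshape a feature matrix into the (N, channels, bands) input array the
# spec expects, validating the layout.
cnn_input_array <- function(spec, fm) {
  nch <- length(fm$channels); nb <- length(fm$bands)
  if (spec$kind == "cnn2d") {
    if (fm$layout != "stacked" || nb != spec$input_map[1] ||
        nch != spec$input_map[2])
      stopf("layout mismatch: spec expects a stacked %d x %d map, features are %s with %d band(s) x %d channel(s)",
            spec$input_map[1], spec$input_map[2], fm$layout, nb, nch)
  } else {
    if (nb != 1 || nch != spec$input_map[2])
      stopf("layout mismatch: spec expects one band x %d channels, features have %d band(s) x %d channel(s)",
            spec$input_map[2], nb, nch)
  }
  array(fm$values, c(nrow(fm$values), nch, nb))
}

adam_step <- function(par, g, st, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(g)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mhat <- st$m[[nm]] / (1 - beta1^t)
    vhat <- st$v[[nm]] / (1 - beta2^t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, st = st)
}

#' Train a CNN on standardized band-power features
#'
#' Minimises binary cross-entropy with Adam over shuffled minibatches,
#' holding out a stratified validation fraction for early stopping on
#' validation loss. Training is fully determined by `cfg$seed`.
#'
#' @param spec a `cnn_spec` from [build_cnn2d()] or [build_cnn1d()].
#' @param fm standardized `eeg_features` whose layout matches the spec
#'   (stacked for 2D, single-band for 1D).
#' @param labels optional 0/1 labels (default `fm$labels`).
#' @param cfg a [train_config()].
#' @return An `eeg_classifier` handle with the trained parameters and the
#'   per-epoch `history` of training/validation loss.
#' @export
train_cnn <- function(spec, fm, labels = NULL, cfg = train_config()) {
  stopifnot(inherits(spec, "cnn_spec"), inherits(fm, "eeg_features"))
  labels <- as.integer(labels %||% fm$labels)
  X <- cnn_input_array(spec, fm)
  N <- dim(X)[1]
  par <- cnn_init_params(spec, substream_seed(cfg$seed, "init"))
  st <- list(m = lapply(par, function(p) p * 0),
             v = lapply(par, function(p) p * 0))
  val_idx <- integer()
  if (cfg$validation_frac > 0 && N >= 20) {
    val_idx <- with_seed(substream_seed(cfg$seed, "val"), {
      unlist(lapply(split(seq_len(N), labels), function(ix)
        sample(ix, max(1, round(length(ix) * cfg$validation_frac)))))
    })
  }
  tr_idx <- setdiff(seq_len(N), val_idx)
  Xtr <- X[tr_idx, , , drop = FALSE]; ytr <- labels[tr_idx]
  Xval <- if (length(val_idx)) X[val_idx, , , drop = FALSE]
  yval <- labels[val_idx]
  best <- list(loss = Inf, par = par, epoch = 0L)
  bad <- 0L
  history <- data.frame()
  t_adam <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(substream_seed(cfg$seed, "shuffle", ep),
                     sample.int(length(tr_idx)))
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, length(ord), by = cfg$batch_size)) {
      bi <- ord[start:min(length(ord), start + cfg$batch_size - 1L)]
      fw <- cnn_forward(spec, par, Xtr[bi, , , drop = FALSE], train = TRUE)
      loss <- bce_loss(fw$prob, ytr[bi])
      if (!is.finite(loss))
        stopf("NaN/Inf loss at epoch %d, batch %d (lr = %g): try a lower learning rate",
              ep, nb + 1L, cfg$learning_rate)
      g <- cnn_backward(spec, par, fw, ytr[bi])
      t_adam <- t_adam + 1L
      upd <- adam_step(par, g, st, cfg$learning_rate, t_adam)
      par <- upd$par; st <- upd$st
      ep_loss <- ep_loss + loss; nb <- nb + 1L
    }
    val_loss <- NA_real_
    if (length(val_idx)) {
      val_loss <- bce_loss(cnn_forward(spec, par, Xval)$prob, yval)
      if (val_loss < best$loss - 1e-6) {
        best <- list(loss = val_loss, par = par, epoch = ep)
        bad <- 0L
      } else bad <- bad + 1L
    }
    history <- rbind(history,
                     data.frame(epoch = ep, train_loss = ep_loss / nb,
                                val_loss = val_loss))
    if (length(val_idx) && bad >= cfg$patience) break
  }
  if (length(val_idx)) par <- best$par
  structure(list(kind = spec$kind, spec = spec, params = par,
                 history = history, config = cfg,
                 feature_names = fm$feature_names, layout = fm$layout,
                 bands = fm$bands, channels = fm$channels),
            class = "eeg_classifier")
}

# Probabilities for a fitted CNN handle on a feature matrix.
cnn_forward_prob <- function(handle, fm) {
  X <- cnn_input_array(handle$spec, fm)
  cnn_forward(handle$spec, handle$params, X)$prob
}
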