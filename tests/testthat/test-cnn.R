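test_that("architecture shape arithmetic matches the layer list", {
  spec <- build_cnn2d(5, 32)
  expect_equal(spec$input_map, c(5, 32))
  # two 2x1 pools on the channel axis: 32 -> 16 -> 8
  expect_equal(pdeeg:::cnn_pooled_height(32), 8)
  expect_equal(pdeeg:::cnn_pooled_height(29), 7)   # floor pooling
  expect_error(build_cnn2d(5, 3), ">= 4")
  spec1 <- build_cnn1d("gamma", 32)
  expect_equal(spec1$input_map, c(1, 32))
  expect_error(build_cnn1d("gamma", 2), ">= 4")
})

test_that("initialisation is seeded and the forward pass emits probabilities", {
  spec <- build_cnn2d(5, 8)
  p1 <- pdeeg:::cnn_init_params(spec, 42)
  p2 <- pdeeg:::cnn_init_params(spec, 42)
  expect_identical(p1, p2)
  p3 <- pdeeg:::cnn_init_params(spec, 43)
  expect_false(identical(p1$W1, p3$W1))

  X0 <- array(0, c(3, 8, 5))
  prob <- pdeeg:::cnn_forward(spec, p1, X0)$prob
  expect_length(prob, 3)
  expect_true(all(prob > 0 & prob < 1))

  # channel permutation changes the output: spatial structure is used
  set.seed(30)
  X <- array(rnorm(3 * 8 * 5), c(3, 8, 5))
  Xp <- X[, c(5, 3, 8, 1, 7, 2, 6, 4), , drop = FALSE]
  expect_false(isTRUE(all.equal(pdeeg:::cnn_forward(spec, p1, X)$prob,
                                pdeeg:::cnn_forward(spec, p1, Xp)$prob)))
})

test_that("gradients from backprop match finite differences", {
  spec <- build_cnn2d(3, 6, conv_filters = c(2L, 3L), fc_units = 4L)
  par <- pdeeg:::cnn_init_params(spec, 5)
  set.seed(31)
  X <- array(rnorm(4 * 6 * 3), c(4, 6, 3))
  y <- c(0, 1, 1, 0)
  fw <- pdeeg:::cnn_forward(spec, par, X, train = TRUE)
  g <- pdeeg:::cnn_backward(spec, par, fw, y)
  eps <- 1e-6
  for (nm in c("W1", "W2", "W3", "W4", "b2")) {
    idx <- sample(length(par[[nm]]), 3)
    for (i in idx) {
      pp <- par; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- par; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (pdeeg:::bce_loss(pdeeg:::cnn_forward(spec, pp, X)$prob, y) -
              pdeeg:::bce_loss(pdeeg:::cnn_forward(spec, pm, X)$prob, y)) /
             (2 * eps)
      expect_lt(abs(num - g[[nm]][i]) / max(abs(num), 1e-4), 1e-3)
    }
  }
})

test_that("training reduces the loss and is reproducible", {
  set.seed(32)
  n <- 60
  vals <- rbind(matrix(rnorm(n / 2 * 40, mean = -1), n / 2, 40),
                matrix(rnorm(n / 2 * 40, mean = 1), n / 2, 40))
  bands <- eeg_bands()$name
  fm <- new_features(vals,
                     feature_names = paste(rep(bands, each = 8),
                                           rep(paste0("ch", 1:8), 5),
                                           sep = "_"),
                     labels = rep(0:1, each = n / 2),
                     subject_ids = paste0("s", seq_len(n)),
                     groups = rep(c("HC", "PD"), each = n / 2),
                     layout = "stacked", bands = bands,
                     channels = paste0("ch", 1:8), standardized = TRUE)
  spec <- build_cnn2d(5, 8)
  cfg <- train_config(epochs = 5, validation_frac = 0, seed = 9)
  h1 <- train_cnn(spec, fm, cfg = cfg)
  expect_lt(tail(h1$history$train_loss, 1), h1$history$train_loss[1])
  h2 <- train_cnn(spec, fm, cfg = cfg)
  expect_identical(predict(h1, fm)$label, predict(h2, fm)$label)
  expect_identical(h1$params, h2$params)
  pred <- predict(h1, fm)
  expect_true(all(pred$prob >= 0 & pred$prob <= 1))
  expect_equal(pred$label, as.integer(pred$prob >= 0.5))

  wrong <- toy_features(matrix(rnorm(30), 10, 3), labels = rep(0:1, 5))
  expect_error(predict(h1, wrong), "layout mismatch")
  expect_error(train_cnn(build_cnn2d(5, 9), fm), "layout mismatch")
})

test_that("the gamma-band 1D CNN beats the delta-band 1D CNN on planted data", {
  pb <- planted_band_features()
  cfg <- train_config(epochs = 8, patience = 3)
  gamma <- evaluate_model(pb$gamma, "cnn1d", "dependent", k = 3, seed = 11,
                          cnn_config = cfg)
  delta <- evaluate_model(pb$delta, "cnn1d", "dependent", k = 3, seed = 11,
                          cnn_config = cfg)
  expect_gt(gamma$summary[["accuracy"]], delta$summary[["accuracy"]])
})
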