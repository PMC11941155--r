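test_that("case definitions pick the published group contrasts", {
  c1 <- case_spec("case1"); c2 <- case_spec("case2"); c3 <- case_spec("case3")
  expect_equal(c1$positive, "PD_ON");  expect_equal(c1$preset, "dataset1")
  expect_equal(c2$positive, "PD_OFF"); expect_equal(c2$preset, "dataset1")
  expect_true("PD" %in% c3$positive);  expect_equal(c3$preset, "dataset2")
  expect_false(any(c1$positive %in% c1$negative))
})

test_that("make_case filters epochs and recordings and relabels them", {
  cfg <- synth_config(dataset_preset("dataset1"), n_pd = 2, n_hc = 2,
                      duration_s = 3, blink_rate = 0, seed = 40)
  recs <- simulate_cohort(cfg)
  kept <- make_case(recs, case_spec("case1"))
  expect_length(kept, 4)                       # 2 HC + 2 PD_ON
  expect_false(any(vapply(kept, `[[`, "", "group") == "PD_OFF"))

  eps <- bind_epochs(lapply(recs, segment, n_epochs = 3))
  e1 <- make_case(eps, case_spec("case1"))
  expect_equal(dim(e1$data)[1], 4 * 3)
  expect_true(all(e1$groups %in% c("HC", "PD_ON")))
  expect_equal(e1$labels, as.integer(e1$groups == "PD_ON"))

  hc_only <- recs[vapply(recs, `[[`, "", "group") == "HC"]
  expect_error(make_case(hc_only, case_spec("case1")), "zero members")
})

test_that("splits have the published sizes and partition the epochs", {
  # label geometry of the 31-recording dual-session cohort: 16 HC + 15 PD
  # sessions x 180 one-second epochs
  labels <- rep(c(0L, 1L), c(16 * 180, 15 * 180))
  fm <- toy_features(matrix(0, length(labels), 1), labels = labels,
                     subject_ids = paste0("s", rep(seq_len(31), each = 180)),
                     standardized = FALSE)
  expect_equal(nrow(fm$values), 5580)
  ho <- split_holdout(fm, test_frac = 0.1, seed = 42)
  expect_length(ho$train, 5022)
  expect_length(ho$test, 558)
  expect_setequal(c(ho$train, ho$test), seq_len(5580))
  expect_length(intersect(ho$train, ho$test), 0)

  folds <- split_subject_dependent(fm, k = 5, seed = 42)
  expect_equal(vapply(folds, length, 0L), rep(1116L, 5))
  expect_setequal(unlist(folds), seq_len(5580))
  expect_identical(folds, split_subject_dependent(fm, k = 5, seed = 42))
  expect_false(identical(folds, split_subject_dependent(fm, 5, seed = 1)))
  expect_error(split_subject_dependent(pdeeg:::subset_features(fm, 1:3), 5),
               "exceeds")
})

test_that("subject-independent folds never leak subjects", {
  labels <- rep(rep(c(0L, 1L), c(3, 4)), each = 10)
  sids <- rep(c(paste0("h", 1:3), paste0("p", 1:2), paste0("p", 1:2)),
              each = 10)                       # p1/p2 have two sessions
  fm <- toy_features(matrix(rnorm(70), 70, 1), labels = labels,
                     subject_ids = sids, standardized = FALSE)
  loso <- split_subject_independent(fm)
  expect_length(loso, 5)                       # 5 distinct subjects
  for (f in loso) {
    te <- unique(fm$subject_ids[f])
    expect_length(te, 1)
    expect_false(te %in% unique(fm$subject_ids[-f]))
  }
  # both sessions of p1 travel together: its fold holds 20 epochs
  sizes <- vapply(loso, length, 0L)
  expect_setequal(sizes, c(10, 10, 10, 20, 20))
  expect_setequal(unlist(loso), seq_len(70))

  one_class <- toy_features(matrix(0, 20, 1), labels = rep(1L, 20),
                            subject_ids = rep(c("a", "b"), each = 10),
                            standardized = FALSE)
  expect_error(split_subject_independent(one_class), "2 subjects per class")
})

test_that("metric arithmetic agrees with a brute-force tally", {
  perfect <- compute_metrics(c(0, 1, 0, 1), c(0, 1, 0, 1), c(0.1, 0.9, 0.2, 0.8))
  expect_equal(unname(perfect$metrics[c("accuracy", "sensitivity",
                                        "specificity", "f1", "auc")]),
               rep(1, 5))

  set.seed(50)
  for (i in 1:100) {
    n <- sample(20:60, 1)
    yt <- sample(0:1, n, replace = TRUE)
    yp <- sample(0:1, n, replace = TRUE)
    m <- compute_metrics(yt, yp)
    # independent tally
    tp <- 0; tn <- 0; fp <- 0; fn <- 0
    for (j in seq_len(n)) {
      if (yt[j] == 1 && yp[j] == 1) tp <- tp + 1
      if (yt[j] == 0 && yp[j] == 0) tn <- tn + 1
      if (yt[j] == 0 && yp[j] == 1) fp <- fp + 1
      if (yt[j] == 1 && yp[j] == 0) fn <- fn + 1
    }
    expect_equal(unname(m$confusion), c(tn, fp, fn, tp))
    expect_equal(sum(m$confusion), n)
    expect_equal(m$metrics[["accuracy"]], (tp + tn) / n)
    if (tp + fn > 0)
      expect_equal(m$metrics[["sensitivity"]], tp / (tp + fn))
    if (tn + fp > 0)
      expect_equal(m$metrics[["specificity"]], tn / (tn + fp))
  }
})

test_that("trapezoidal AUC equals the normalised Mann-Whitney statistic", {
  set.seed(51)
  for (i in 1:20) {
    n <- 80
    yt <- sample(0:1, n, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(yt)) < 2) next
    sc <- rnorm(n) + yt * runif(1, 0, 2)
    auc <- compute_metrics(yt, as.integer(sc > 0), sc)$metrics[["auc"]]
    r <- rank(sc)                              # midranks handle ties
    np <- sum(yt == 1); nn <- sum(yt == 0)
    u <- sum(r[yt == 1]) - np * (np + 1) / 2
    expect_lt(abs(auc - u / (np * nn)), 1e-10)
  }

  # random balanced scores: AUC near 0.5
  yt <- rep(0:1, 1000)
  set.seed(52)
  sc <- rnorm(2000)
  auc <- compute_metrics(yt, as.integer(sc > 0), sc)$metrics[["auc"]]
  sd_auc <- sqrt((1000 + 1000 + 1) / (12 * 1000 * 1000))
  expect_lt(abs(auc - 0.5), 3 * sd_auc)

  # single-class truth: AUC undefined, reported as missing
  m <- compute_metrics(rep(1, 5), rep(1, 5), runif(5))
  expect_true(is.na(m$metrics[["auc"]]))
})

test_that("the ablation table reproduces the planted band ordering", {
  pb <- planted_band_features()
  cfg <- train_config(epochs = 8, patience = 3)
  ab <- run_ablation(pb, bands = c("delta", "theta", "alpha", "gamma"),
                     k = 3, seed = 5, cnn_config = cfg)
  expect_equal(nrow(ab), 5)                    # 4 x 1D + the stacked 2D
  acc <- setNames(ab$accuracy, paste(ab$model, ab$band))
  # stacked model sees every band: at least as good as the low bands alone
  expect_gte(acc[["cnn2d all"]],
             max(acc[c("cnn1d delta", "cnn1d theta", "cnn1d alpha")]))
  expect_gt(acc[["cnn1d gamma"]], acc[["cnn1d delta"]])
  # fixed seeds give an identical table (checked on the cheapest slice)
  a1 <- run_ablation(pb, bands = "gamma", k = 2, seed = 5,
                     cnn_config = train_config(epochs = 2, patience = 1))
  a2 <- run_ablation(pb, bands = "gamma", k = 2, seed = 5,
                     cnn_config = train_config(epochs = 2, patience = 1))
  expect_identical(a1, a2)
})
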