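test_that("binary leave-one-clip-out uses 15 folds of 686 train / 49 test epochs", {
  fm <- make_protocol_features(signal = 1.5, seed = 101)
  r <- binary_leave_one_clip_out(fm)
  expect_equal(nrow(r$folds), 15)
  expect_true(all(r$folds$n_train == 686))
  expect_true(all(r$folds$n_test == 49))
  expect_equal(sum(r$confusion), 15 * 49)
  expect_false(any(duplicated(r$folds$test_clip)))
  # neutral clips are excluded entirely
  expect_false(any(r$folds$test_clip %in% 4:6))
})

test_that("a perfectly separable feature yields 100% on every binary fold", {
  fm <- make_protocol_features(signal = 0, seed = 102)
  fm$X[, 1] <- ifelse(fm$meta$emotion == "joy", 10, -10) + rnorm(nrow(fm$X), 0, 0.01)
  r <- binary_leave_one_clip_out(fm)
  expect_true(all(r$folds$accuracy == 1))
  expect_equal(r$accuracy, 1)
})

test_that("pure-noise features give binary accuracy near the majority-class rate", {
  accs <- vapply(1:5, function(s)
    binary_leave_one_clip_out(make_protocol_features(signal = 0,
                                                     epochs_per_clip = 15,
                                                     seed = 110 + s))$accuracy,
    numeric(1))
  expect_lt(abs(mean(accs) - 12 / 15), 0.06)
})

test_that("six-class CV uses 3 folds of 588 train / 294 test and balanced clips", {
  fm <- make_protocol_features(signal = 2, seed = 103)
  r <- six_class_cv(fm)
  expect_equal(nrow(r$folds), 3)
  expect_true(all(r$folds$n_train == 588))
  expect_true(all(r$folds$n_test == 294))
  expect_equal(sum(r$confusion), 3 * 294)
  expect_equal(dim(r$confusion), c(6, 6))
})

test_that("six-class accuracy spans chance (noise) to perfect (encodable labels)", {
  accs <- vapply(1:5, function(s)
    six_class_cv(make_protocol_features(signal = 0, epochs_per_clip = 12,
                                        seed = 120 + s))$accuracy,
    numeric(1))
  expect_lt(abs(mean(accs) - 1 / 6), 0.07)

  fm <- make_protocol_features(signal = 0, epochs_per_clip = 12, seed = 104)
  fm$X[, 1] <- match(fm$meta$emotion, emotion_levels()) * 10 +
    rnorm(nrow(fm$X), 0, 0.01)
  expect_equal(six_class_cv(fm)$accuracy, 1)
})

test_that("missing or incomplete clips raise structural errors", {
  fm <- make_protocol_features(seed = 105)
  broken <- filter_epochs(fm)
  keep <- broken$meta$clip_id != 7
  broken$X <- broken$X[keep, ]; broken$meta <- broken$meta[keep, ]
  expect_error(binary_leave_one_clip_out(broken), "clip")
  expect_error(six_class_cv(broken), "clip")
})

test_that("cross-paradigm training on movie and testing on identical recall features reduces to resubstitution", {
  movie <- make_protocol_features(signal = 1, epochs_per_clip = 10, seed = 106)
  recall <- movie
  recall$meta$paradigm <- "recall"
  r <- cross_paradigm(movie, recall, scheme = "six_class")
  expect_equal(r$folds$n_train, 18 * 10)
  expect_equal(r$folds$n_test, 18 * 10)
  # resubstitution: same fitted model applied to its own training set
  fit <- eegemotion:::fit_fold(movie$X, movie$meta$emotion, movie$X)
  expect_equal(r$folds$accuracy, mean(fit$pred == movie$meta$emotion))

  rb <- cross_paradigm(movie, recall, scheme = "binary")
  expect_equal(rb$folds$n_train, 15 * 10)

  other <- make_protocol_features(signal = 1, epochs_per_clip = 10, seed = 107)
  other$meta$clip_id <- other$meta$clip_id + 100
  expect_error(cross_paradigm(movie, other), "paradigm mismatch")
})

test_that("confusion-matrix metrics match hand-computed values", {
  d <- diag(c(5, 8, 2))
  m <- metrics_from_confusion(d)
  expect_equal(m$accuracy, 100)
  expect_true(all(m$per_class$f1 == 1))
  expect_error(metrics_from_confusion(matrix(0, 2, 2)), "all-zero")
  expect_error(metrics_from_confusion(matrix(1:6, 2, 3)), "square")

  # worked 2x2 example: precision 0.8 (8 of 10), recall 8/9
  cm <- matrix(c(8, 1, 2, 5), 2, 2)
  m2 <- metrics_from_confusion(cm)
  expect_equal(m2$per_class$precision[1], 0.8)
  expect_equal(m2$per_class$recall[1], 8 / 9)
  expect_equal(m2$per_class$f1[1], 2 * 0.8 * (8 / 9) / (0.8 + 8 / 9))
})

test_that("pooled confusion accuracy equals the epoch-weighted mean of fold accuracies", {
  fm <- make_protocol_features(signal = 0.8, epochs_per_clip = 10, seed = 108)
  r <- six_class_cv(fm)
  pooled <- metrics_from_confusion(r$confusion)$accuracy / 100
  weighted <- sum(r$folds$accuracy * r$folds$n_test) / sum(r$folds$n_test)
  expect_equal(pooled, weighted, tolerance = 1e-12)
})

test_that("ROC/AUC behaves at the extremes, under permutation, and against pROC", {
  y <- rep(c("positive", "negative"), each = 50)
  s <- as.numeric(y == "positive")
  expect_equal(roc_auc(s, y)$auc, 1)
  expect_equal(roc_auc(-s, y)$auc, 0)

  set.seed(131)
  s2 <- rnorm(1e4)
  y2 <- sample(y, 1e4, TRUE)
  a <- roc_auc(s2, y2)$auc
  expect_gt(a, 0.48); expect_lt(a, 0.52)
  expect_equal(roc_auc(-s2, y2)$auc, 1 - a, tolerance = 1e-12)
  expect_error(roc_auc(1:5, rep("positive", 5)), "both classes")

  set.seed(132)
  s3 <- rnorm(200); y3 <- sample(y, 200, TRUE)
  ref <- as.numeric(pROC::auc(pROC::roc(response = y3, predictor = s3,
                                        levels = c("negative", "positive"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(s3, y3)$auc, ref, tolerance = 1e-12)
})

test_that("cohort summaries pool confusions and report mean/sd in percent", {
  rs <- lapply(1:3, function(s)
    binary_leave_one_clip_out(make_protocol_features(signal = 1.2,
                                                     epochs_per_clip = 8,
                                                     seed = 140 + s)))
  rep_ <- summarize_protocol(rs)
  expect_length(rep_$subject_accuracy, 3)
  expect_equal(rep_$mean_accuracy, mean(rep_$subject_accuracy))
  expect_equal(sum(rep_$confusion), 3 * 15 * 8)
  expect_true(rep_$roc$auc > 0.5)
  expect_equal(rep_$metrics$accuracy,
               metrics_from_confusion(rep_$confusion)$accuracy)
})
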