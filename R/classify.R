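#' @importFrom e1071 svm
NULL

# z-score columns by training statistics, fit a linear SVM (LIBSVM via
# e1071, default parameters), predict the test set. For binary problems the
# decision values are oriented so larger = `positive`.
fit_fold <- function(Xtr, ytr, Xte, positive = NULL) {
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  Ztr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
  Zte <- sweep(sweep(Xte, 2, mu), 2, sdv, "/")
  ytr <- factor(ytr)
  model <- e1071::svm(Ztr, ytr, kernel = "linear", scale = FALSE)
  pred <- stats::predict(model, Zte, decision.values = !is.null(positive))
  scores <- NULL
  if (!is.null(positive)) {
    dv <- attr(pred, "decision.values")
    pair <- strsplit(colnames(dv)[1], "/")[[1]]
    scores <- if (pair[1] == positive) dv[, 1] else -dv[, 1]
  }
  list(pred = as.character(pred), scores = scores)
}

check_clip_structure <- function(meta, emotions) {
  per_emotion <- lapply(emotions, function(e) sort(unique(meta$clip_id[meta$emotion == e])))
  names(per_emotion) <- emotions
  n_clips <- vapply(per_emotion, length, integer(1))
  if (any(n_clips == 0) || length(unique(n_clips)) != 1) {
    stop("missing clip(s): emotions have unequal clip counts (",
         paste(sprintf("%s: %d", emotions, n_clips), collapse = ", "), ")")
  }
  counts <- table(meta$clip_id)
  if (length(unique(as.integer(counts))) != 1) {
    stop("clip(s) with incomplete epochs: clip_id ",
         paste(names(counts)[counts != max(counts)], collapse = ", "))
  }
  per_emotion
}

subject_result <- function(task, scheme, folds, confusion, scores) {
  structure(list(task = task, scheme = scheme, folds = folds,
                 accuracy = mean(folds$accuracy), confusion = confusion,
                 scores = scores),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("<protocol_result> %s / %s: %d folds, accuracy %.2f%%\n",
              x$task, x$scheme, nrow(x$folds), 100 * x$accuracy))
  invisible(x)
}

empty_confusion <- function(labels) {
  matrix(0L, length(labels), length(labels),
         dimnames = list(predicted = labels, true = labels))
}

accumulate_confusion <- function(conf, pred, truth) {
  for (i in seq_along(pred)) conf[pred[i], truth[i]] <- conf[pred[i], truth[i]] + 1L
  conf
}

#' Binary leave-one-clip-out classification for one subject
#'
#' Positive = epochs from the `positive` emotion's clips, negative = epochs
#' from the `negative` emotions' clips; other emotions (neutral by default)
#' are excluded. One fold per eligible clip: its epochs form the test set
#' and all other eligible clips form the training set (with the default
#' 3 + 12 clips of 49 epochs: train 686, test 49). The subject accuracy is
#' the mean of the fold accuracies.
#'
#' @param fm a `feature_matrix` restricted to one subject and one paradigm.
#' @param positive emotion treated as the positive class.
#' @param negative emotions pooled into the negative class.
#' @return a `protocol_result` with per-fold accuracies, the pooled 2x2
#'   predicted x true confusion matrix, and oriented decision scores.
#' @export
binary_leave_one_clip_out <- function(fm, positive = "joy",
                                      negative = c("sad", "disgust",
                                                   "anger", "fear")) {
  meta <- fm$meta
  keep <- meta$emotion %in% c(positive, negative)
  meta <- meta[keep, , drop = FALSE]
  X <- fm$X[keep, , drop = FALSE]
  check_clip_structure(meta, c(positive, negative))
  y <- ifelse(meta$emotion == positive, "positive", "negative")
  clips <- sort(unique(meta$clip_id))
  conf <- empty_confusion(c("positive", "negative"))
  folds <- data.frame(fold = seq_along(clips), test_clip = clips,
                      n_train = NA_integer_, n_test = NA_integer_,
                      accuracy = NA_real_)
  all_scores <- NULL
  for (i in seq_along(clips)) {
    te <- meta$clip_id == clips[i]
    fit <- fit_fold(X[!te, , drop = FALSE], y[!te], X[te, , drop = FALSE],
                    positive = "positive")
    folds$n_train[i] <- sum(!te)
    folds$n_test[i] <- sum(te)
    folds$accuracy[i] <- mean(fit$pred == y[te])
    conf <- accumulate_confusion(conf, fit$pred, y[te])
    all_scores <- rbind(all_scores,
                        data.frame(score = fit$scores, truth = y[te]))
  }
  subject_result("within_paradigm", "binary", folds, conf, all_scores)
}

#' Six-class cross-validation over clip positions for one subject
#'
#' Folds are formed over within-emotion clip positions: fold `j` tests the
#' `j`-th clip of every emotion (6 clips) and trains on the remaining
#' clips (2 per emotion with the default 3 clips/emotion: train 588 epochs,
#' test 294). The subject accuracy is the mean of the fold accuracies.
#'
#' @param fm a `feature_matrix` restricted to one subject and one paradigm.
#' @param emotions the six class labels (ordering fixes the confusion
#'   matrix layout).
#' @return a `protocol_result` with the pooled 6x6 confusion matrix.
#' @export
six_class_cv <- function(fm, emotions = emotion_levels()) {
  meta <- fm$meta
  per_emotion <- check_clip_structure(meta, emotions)
  n_folds <- length(per_emotion[[1]])
  conf <- empty_confusion(emotions)
  folds <- data.frame(fold = seq_len(n_folds), n_train = NA_integer_,
                      n_test = NA_integer_, accuracy = NA_real_)
  for (j in seq_len(n_folds)) {
    test_clips <- vapply(per_emotion, `[`, numeric(1), j)
    te <- meta$clip_id %in% test_clips
    fit <- fit_fold(fm$X[!te, , drop = FALSE], meta$emotion[!te],
                    fm$X[te, , drop = FALSE])
    folds$n_train[j] <- sum(!te)
    folds$n_test[j] <- sum(te)
    folds$accuracy[j] <- mean(fit$pred == meta$emotion[te])
    conf <- accumulate_confusion(conf, fit$pred, meta$emotion[te])
  }
  subject_result("within_paradigm", "six_class", folds, conf, NULL)
}

#' Cross-paradigm classification for one subject
#'
#' Trains on all movie-paradigm epochs and tests on all recall-paradigm
#' epochs (a single fold; 882 train / 882 test with the default protocol).
#' The binary scheme restricts both sides to the positive + negative clips
#' (15 of 18).
#'
#' @param movie_fm,recall_fm `feature_matrix` objects for one subject's
#'   movie and recall epochs; both paradigms must cover the same clips.
#' @param scheme `"six_class"` or `"binary"`.
#' @param positive,negative binary class definition (see
#'   [binary_leave_one_clip_out()]).
#' @param emotions six-class label order.
#' @return a `protocol_result` (single fold).
#' @export
cross_paradigm <- function(movie_fm, recall_fm,
                           scheme = c("six_class", "binary"),
                           positive = "joy",
                           negative = c("sad", "disgust", "anger", "fear"),
                           emotions = emotion_levels()) {
  scheme <- match.arg(scheme)
  if (!setequal(movie_fm$meta$clip_id, recall_fm$meta$clip_id)) {
    stop("paradigm mismatch: movie and recall cover different clips")
  }
  if (scheme == "binary") {
    movie_fm <- filter_epochs(movie_fm, emotion = c(positive, negative))
    recall_fm <- filter_epochs(recall_fm, emotion = c(positive, negative))
    ytr <- ifelse(movie_fm$meta$emotion == positive, "positive", "negative")
    yte <- ifelse(recall_fm$meta$emotion == positive, "positive", "negative")
    fit <- fit_fold(movie_fm$X, ytr, recall_fm$X, positive = "positive")
    conf <- accumulate_confusion(empty_confusion(c("positive", "negative")),
                                 fit$pred, yte)
    scores <- data.frame(score = fit$scores, truth = yte)
  } else {
    ytr <- movie_fm$meta$emotion
    yte <- recall_fm$meta$emotion
    fit <- fit_fold(movie_fm$X, ytr, recall_fm$X)
    conf <- accumulate_confusion(empty_confusion(emotions), fit$pred, yte)
    scores <- NULL
  }
  folds <- data.frame(fold = 1L, n_train = nrow(movie_fm$X),
                      n_test = nrow(recall_fm$X),
                      accuracy = mean(fit$pred == yte))
  subject_result("cross_paradigm", scheme, folds, conf, scores)
}

#' Accuracy and per-class precision/recall/F1 from a confusion matrix
#'
#' @param mat square matrix of non-negative integer counts, rows =
#'   predicted class, columns = true class, identically ordered.
#' @return list with `accuracy` (percent), and `per_class` data.frame with
#'   `class`, `precision`, `recall`, `f1` (`f1 = 0` when precision + recall
#'   is 0).
#' @export
metrics_from_confusion <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("confusion matrix must be square")
  if (any(mat < 0)) stop("negative counts")
  total <- sum(mat)
  if (total == 0) stop("all-zero confusion matrix")
  acc <- sum(diag(mat)) / total * 100
  prec <- diag(mat) / pmax(rowSums(mat), 1e-300)
  rec <- diag(mat) / pmax(colSums(mat), 1e-300)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  cls <- if (!is.null(colnames(mat))) colnames(mat) else
    as.character(seq_len(ncol(mat)))
  list(accuracy = acc,
       per_class = data.frame(class = cls, precision = as.numeric(prec),
                              recall = as.numeric(rec), f1 = as.numeric(f1),
                              row.names = NULL))
}

#' ROC curve and AUC from decision scores
#'
#' Threshold sweep over the unique scores (larger score = more positive);
#' AUC by the trapezoid rule.
#'
#' @param scores numeric decision values.
#' @param labels class labels, same length.
#' @param positive label counted as positive.
#' @return list with `points` (data.frame `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels, positive = "positive") {
  if (length(scores) != length(labels)) stop("length mismatch")
  pos <- labels == positive
  if (!any(pos) || all(pos)) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- c(s[-1] != s[-length(s)], TRUE)   # collapse tied thresholds
  tpr <- c(0, tp[last] / sum(pos))
  fpr <- c(0, fp[last] / sum(!pos))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr,
                           threshold = c(Inf, s[last])),
       auc = auc)
}

#' Summarize per-subject protocol results into a cohort report
#'
#' @param results list of `protocol_result` objects from the same protocol.
#' @return a `classification_report`: subject accuracies, their mean and sd
#'   (percent), the pooled predicted x true confusion matrix, per-class F1,
#'   and pooled ROC/AUC when decision scores are available.
#' @export
summarize_protocol <- function(results) {
  stopifnot(length(results) >= 1)
  acc <- vapply(results, `[[`, numeric(1), "accuracy") * 100
  conf <- Reduce(`+`, lapply(results, `[[`, "confusion"))
  met <- metrics_from_confusion(conf)
  scores <- do.call(rbind, lapply(results, `[[`, "scores"))
  roc <- if (!is.null(scores))
    roc_auc(scores$score, scores$truth, positive = "positive") else NULL
  structure(list(task = results[[1]]$task, scheme = results[[1]]$scheme,
                 subject_accuracy = acc, mean_accuracy = mean(acc),
                 sd_accuracy = stats::sd(acc), confusion = conf,
                 metrics = met, roc = roc),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %s / %s: %.2f%% (SD %.2f) over %d subjects",
              x$task, x$scheme, x$mean_accuracy,
              ifelse(is.na(x$sd_accuracy), 0, x$sd_accuracy),
              length(x$subject_accuracy)))
  if (!is.null(x$roc)) cat(sprintf(", AUC %.4f", x$roc$auc))
  cat("\n")
  invisible(x)
}
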