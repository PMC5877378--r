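# Shared fixtures: all built in code at test time.

# Small 10-channel montage containing the frontal surrogate channels and
# several default effect channels.
tiny_channels <- c("FP1", "FP2", "AF7", "T7", "T8", "TP8", "O1", "Oz",
                   "C3", "C4")

# A compact simulation: full six-emotion / dual-paradigm trial structure,
# short trials so the whole pipeline runs in seconds.
tiny_config <- function(seed = 11, ...) {
  args <- list(trial_seconds = 4, rest_seconds = 6, pre_trial_seconds = 2,
               channels = tiny_channels,
               effect_channels = c("T7", "T8", "AF7"),
               seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# A bare recording with hand-set annotations (1 channel unless given).
make_recording <- function(n_channels = 1, total_s, trials, fs = 512,
                           data = NULL, seed = 5) {
  lay <- channel_layout()[seq_len(n_channels), , drop = FALSE]
  if (is.null(data)) {
    set.seed(seed)
    data <- matrix(rnorm(n_channels * total_s * fs), n_channels)
  }
  raw_recording(data, fs, lay, trials, subject_id = 99)
}

trial_annotations <- function(onsets, durations,
                              paradigm = "movie",
                              emotions = NULL, clip_ids = NULL) {
  n <- length(onsets)
  data.frame(trial_index = seq_len(n),
             paradigm = rep(paradigm, length.out = n),
             clip_id = if (is.null(clip_ids)) seq_len(n) else clip_ids,
             emotion = if (is.null(emotions))
               rep(emotion_levels(), length.out = n) else emotions,
             onset_s = onsets, duration_s = durations,
             stringsAsFactors = FALSE)
}

# A feature_matrix with the full protocol's clip/epoch structure but
# synthetic feature values: `signal` adds a class-separable component.
make_protocol_features <- function(n_clips_per_emotion = 3,
                                   epochs_per_clip = 49,
                                   n_features = 10, signal = 0,
                                   paradigm = "movie", subject_id = 1,
                                   seed = 1) {
  set.seed(seed)
  emotions <- rep(emotion_levels(), each = n_clips_per_emotion)
  n_clips <- length(emotions)
  meta <- data.frame(
    subject_id = subject_id,
    trial_index = rep(seq_len(n_clips), each = epochs_per_clip),
    clip_id = rep(seq_len(n_clips), each = epochs_per_clip),
    emotion = rep(emotions, each = epochs_per_clip),
    paradigm = paradigm,
    epoch_index = rep(seq_len(epochs_per_clip), n_clips),
    stringsAsFactors = FALSE)
  X <- matrix(rnorm(nrow(meta) * n_features), nrow(meta))
  if (signal != 0) {
    class_idx <- match(meta$emotion, emotion_levels())
    for (j in seq_len(min(3, n_features))) {
      X[, j] <- X[, j] + signal * class_idx * j
    }
  }
  colnames(X) <- feature_names(channel_layout()[1:2, ])[seq_len(n_features)]
  structure(list(X = X, meta = meta, layout = channel_layout()[1:2, ]),
            class = "feature_matrix")
}

# Independent greedy MRMR oracle: direct re-implementation with explicit
# criterion evaluation (no incremental caching), used to cross-check
# mrmr_rank().
mrmr_bruteforce <- function(codes, labels, k) {
  nf <- ncol(codes)
  selected <- integer(0)
  for (step in seq_len(k)) {
    best <- NA; best_val <- -Inf
    for (j in seq_len(nf)) {
      if (j %in% selected) next
      rel <- mutual_information(codes[, j], labels)
      red <- if (length(selected) == 0) 0 else
        mean(vapply(selected, function(i)
          mutual_information(codes[, j], codes[, i]), numeric(1)))
      val <- rel - red
      if (val > best_val + 1e-12) { best_val <- val; best <- j }
    }
    selected <- c(selected, best)
  }
  selected
}

# Epoch set built directly from an array (bypasses segmentation).
make_epoch_set <- function(data, fs = 512, layout = NULL, meta = NULL) {
  n_ep <- dim(data)[3]
  if (is.null(layout)) layout <- channel_layout()[seq_len(dim(data)[1]), ]
  if (is.null(meta)) {
    meta <- data.frame(subject_id = 1, trial_index = 1, clip_id = 1,
                       emotion = rep(emotion_levels(),
                                     length.out = n_ep),
                       paradigm = "movie", epoch_index = seq_len(n_ep),
                       stringsAsFactors = FALSE)
  }
  structure(list(data = data, meta = meta, fs = fs, layout = layout),
            class = "epoch_set")
}
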