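#' Construct a raw multichannel EEG recording
#'
#' The container passed between simulation, preprocessing and epoching:
#' a channels x samples matrix in microvolts plus sampling rate, montage
#' and trial-block annotations.
#'
#' @param data numeric matrix, channels x samples (µV); rownames are ignored,
#'   channel identity comes from `layout`.
#' @param fs sampling rate in Hz.
#' @param layout data.frame with `name`, `x`, `y` (see [channel_layout()]);
#'   must have as many rows as `data`.
#' @param annotations data.frame of trial blocks with columns `trial_index`,
#'   `paradigm` ("movie" or "recall"), `clip_id`, `emotion`, `onset_s`,
#'   `duration_s`. May have zero rows.
#' @param subject_id identifier for the subject.
#' @return an object of class `raw_recording`.
#' @export
raw_recording <- function(data, fs, layout, annotations = NULL,
                          subject_id = NA) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric channels x samples matrix")
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("`fs` must be a single positive number")
  }
  if (nrow(layout) != nrow(data)) {
    stop("layout has ", nrow(layout), " channels but data has ", nrow(data))
  }
  if (anyDuplicated(layout$name)) stop("duplicate channel names in layout")
  if (is.null(annotations)) {
    annotations <- empty_annotations()
  }
  validate_annotations(annotations, n_samples = ncol(data), fs = fs)
  structure(list(data = data, fs = fs, layout = layout,
                 annotations = annotations, subject_id = subject_id),
            class = "raw_recording")
}

empty_annotations <- function() {
  data.frame(trial_index = integer(), paradigm = character(),
              clip_id = integer(), emotion = character(),
              onset_s = numeric(), duration_s = numeric(),
              stringsAsFactors = FALSE)
}

validate_annotations <- function(ann, n_samples, fs) {
  needed <- c("trial_index", "paradigm", "clip_id", "emotion",
              "onset_s", "duration_s")
  if (!all(needed %in% names(ann))) {
    stop("annotations missing column(s): ",
         paste(setdiff(needed, names(ann)), collapse = ", "))
  }
  if (nrow(ann) == 0) return(invisible(ann))
  if (any(!ann$paradigm %in% c("movie", "recall"))) {
    stop("paradigm must be 'movie' or 'recall'")
  }
  ends <- ann$onset_s + ann$duration_s
  if (any(ann$onset_s < 0) || any(ends > n_samples / fs + 1e-9)) {
    stop("annotation(s) extend beyond the recorded span")
  }
  invisible(ann)
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> subject %s: %d channels x %d samples @ %g Hz (%.1f s), %d trial blocks\n",
              as.character(x$subject_id), nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs, nrow(x$annotations)))
  invisible(x)
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples @ %g Hz\n",
              dim(x$data)[3], dim(x$data)[1], dim(x$data)[2], x$fs))
  invisible(x)
}

channel_index <- function(recording, names) {
  idx <- match(names, recording$layout$name)
  if (anyNA(idx)) {
    stop("channel(s) not in layout: ",
         paste(names[is.na(idx)], collapse = ", "))
  }
  idx
}

sample_range <- function(onset_s, duration_s, fs) {
  from <- round(onset_s * fs) + 1L
  to <- from + round(duration_s * fs) - 1L
  c(from, to)
}
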