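# Published summary tables from the 30-participant movie/recall emotion
# study this pipeline models. The real EEG recordings are not publicly
# deposited; these printed summaries are the only quantities from the
# original cohort that can be recomputed, and they anchor the worked
# examples for metrics_from_confusion() and the cohort averaging.

#' Published per-subject accuracy table of the reference cohort
#'
#' Per-subject classification accuracies (percent) reported for the
#' 30-participant study: binary (positive vs negative) and six-class
#' schemes, each under movie-induced, self-induced and cross-paradigm
#' (train movie, test recall) tasks.
#'
#' @return data.frame with columns `subject`, `scheme` (`"binary"` or
#'   `"six_class"`), `movie`, `self`, `cross`.
#' @export
reference_subject_accuracies <- function() {
  utils::read.csv(system.file("extdata", "reference_subject_accuracies.csv",
                              package = "eegemotion"))
}

#' Published pooled binary confusion matrices of the reference cohort
#'
#' Pooled predicted x true counts over all 30 subjects (15 eligible clips
#' x 49 epochs x 30 subjects = 22,050 epochs per task) for the binary
#' discrimination of positive (joy) from negative emotions.
#'
#' @return named list of three 2x2 matrices (`movie`, `self`, `cross`),
#'   rows = predicted, columns = true, order positive then negative.
#' @export
reference_confusions <- function() {
  mk <- function(pp, pn, np, nn) {
    matrix(c(pp, np, pn, nn), 2, 2,
           dimnames = list(predicted = c("positive", "negative"),
                           true = c("positive", "negative")))
  }
  list(movie = mk(2788, 1200, 1622, 16440),
       self  = mk(2667, 1044, 1743, 16596),
       cross = mk(2578, 2902, 1832, 14738))
}
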