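#' Standard 61-channel 10-20 scalp layout
#'
#' Returns the electrode montage used throughout the package: a 62-electrode
#' extended 10-20 cap recorded against an Fz reference with AFz as ground,
#' leaving 61 effective channels. Positions are schematic 2D projections onto
#' the unit head disc (nose up, x rightward), suitable for topographic
#' interpolation and for defining the frontal/temporal/occipital groupings
#' the emotion analysis refers to.
#'
#' @param channels optional character vector selecting a subset of channels
#'   (in the order given); defaults to the full 61-channel montage.
#' @return a data.frame with columns `name`, `x`, `y`, one row per electrode.
#' @export
#' @examples
#' lay <- channel_layout()
#' nrow(lay)  # 61
channel_layout <- function(channels = NULL) {
  path <- system.file("extdata", "layout_10_20_61.csv", package = "eegemotion")
  lay <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(channels)) {
    missing <- setdiff(channels, lay$name)
    if (length(missing) > 0) {
      stop("unknown channel(s): ", paste(missing, collapse = ", "))
    }
    lay <- lay[match(channels, lay$name), , drop = FALSE]
    rownames(lay) <- NULL
  }
  lay
}

#' Frequency bands used for differential-entropy features
#'
#' The five conventional EEG rhythms, as half-open `(low, high]` intervals
#' in Hz: delta 1-4, theta 4-8, alpha 8-12, beta 12-30, gamma 30-64.
#'
#' @return named list of `c(low, high)` pairs in Hz.
#' @export
eeg_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 12),
       beta = c(12, 30), gamma = c(30, 64))
}

#' Canonical six-emotion label set
#'
#' Factor levels, in protocol order, for the six discrete emotions elicited
#' by the movie/recall paradigm.
#' @return character vector of length 6.
#' @export
emotion_levels <- function() {
  c("joy", "neutral", "sad", "disgust", "anger", "fear")
}
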