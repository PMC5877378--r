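#' Zero-phase band-pass filter a recording
#'
#' 4th-order Butterworth band-pass applied forward-backward
#' ([signal::filtfilt()]), so the filter is zero-phase and the effective
#' magnitude response is the squared Butterworth response. Defaults match
#' the preprocessing band of 0.1-80 Hz.
#'
#' @param recording a [raw_recording()].
#' @param low,high band edges in Hz; require `0 < low < high < fs/2`.
#' @param order filter order of the underlying Butterworth design.
#' @return the filtered recording (length, layout and annotations preserved).
#' @export
bandpass <- function(recording, low = 0.1, high = 80, order = 4) {
  stopifnot(inherits(recording, "raw_recording"))
  fs <- recording$fs
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("invalid band edges: need 0 < low < high < fs/2 (fs = ", fs, ")")
  }
  flt <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  pad <- min(ncol(recording$data) - 1, round(2 * fs / low))
  for (ch in seq_len(nrow(recording$data))) {
    recording$data[ch, ] <- filtfilt_fast(flt$b, flt$a,
                                          recording$data[ch, ], pad)
  }
  recording
}

# Zero-phase IIR filtering: odd-reflection padding at both ends, then a
# forward and a backward pass, each implemented as an FIR convolution
# followed by the recursive (AR) part via stats::filter (both C loops).
filtfilt_fast <- function(b, a, x, pad) {
  n <- length(x)
  p <- max(0L, min(n - 1L, as.integer(pad)))
  z <- if (p > 0) {
    c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  } else x
  nb <- length(b)
  one_pass <- function(z) {
    v <- stats::filter(c(numeric(nb - 1), z), b, method = "convolution",
                       sides = 1)[nb:(length(z) + nb - 1)]
    as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  y <- rev(one_pass(rev(one_pass(z))))
  y[(p + 1):(p + n)]
}

#' Theoretical zero-phase band-pass power response
#'
#' Magnitude-squared response of the forward-backward Butterworth filter
#' used by [bandpass()], evaluated at `freq` Hz. Exposed so tests and users
#' can predict the attenuation of out-of-band components.
#'
#' @inheritParams bandpass
#' @param freq frequencies (Hz) at which to evaluate.
#' @param fs sampling rate in Hz.
#' @return amplitude gain (|H|^2 of the single-pass filter) per frequency.
#' @export
bandpass_gain <- function(freq, low = 0.1, high = 80, fs = 512, order = 4) {
  flt <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  z <- exp(-1i * 2 * pi * freq / fs)
  # rational transfer function in powers of z^-1
  h <- vapply(seq_along(z), function(i) {
    num <- sum(flt$b * z[i]^(seq_along(flt$b) - 1))
    den <- sum(flt$a * z[i]^(seq_along(flt$a) - 1))
    num / den
  }, complex(1))
  Mod(h)^2
}

# Symmetric fixed-point FastICA (logcosh contrast) on a channels x samples
# matrix. Returns sources S (n_comp x samples), the unmixing matrix applied
# to centered data, and the mixing matrix for reconstruction.
fast_ica <- function(X, n_components, seed = 1, max_iter = 200, tol = 1e-4) {
  n_ch <- nrow(X)
  ns <- ncol(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- tcrossprod(Xc) / ns
  eg <- eigen(C, symmetric = TRUE)
  if (eg$values[n_components] < 1e-12 * eg$values[1]) {
    vars <- diag(C)
    worst <- order(vars)[seq_len(min(5, n_ch))]
    stop("rank-deficient data: cannot extract ", n_components,
         " components; lowest-variance channels: ",
         paste(rownames(X)[worst], collapse = ", "))
  }
  K <- diag(1 / sqrt(eg$values[1:n_components]), n_components) %*%
    t(eg$vectors[, 1:n_components, drop = FALSE])
  Z <- K %*% Xc
  set.seed(as.integer(seed %% 2147483647))
  W <- matrix(stats::rnorm(n_components^2), n_components)
  sym_decorrelate <- function(W) {
    s <- eigen(W %*% t(W), symmetric = TRUE)
    s$vectors %*% diag(1 / sqrt(pmax(s$values, 1e-300)),
                       n_components) %*% t(s$vectors) %*% W
  }
  W <- sym_decorrelate(W)
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    gprime <- rowMeans(1 - G^2)
    W1 <- G %*% t(Z) / ns - diag(gprime, n_components) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(1 - abs(rowSums(W1 * W))))
    W <- W1
    if (delta < tol) break
  }
  Wk <- W %*% K                       # sources = Wk %*% centered data
  sv <- svd(Wk)
  mixing <- sv$v %*% diag(1 / sv$d, length(sv$d)) %*% t(sv$u)
  list(S = Wk %*% Xc, unmixing = Wk, mixing = mixing, means = mu,
       iterations = it)
}

#' Remove ocular artifacts by independent component analysis
#'
#' Decomposes the recording into independent components (symmetric
#' fixed-point ICA, logcosh contrast), flags components whose time course
#' correlates (|r| > `threshold`) with a surrogate electrooculogram — the
#' mean of the frontal-pole channels band-limited to 0.5-4 Hz — zeroes the
#' flagged components, and reconstructs the signal. The flagging rule is an
#' automatic, reproducible stand-in for visual component selection.
#'
#' @param recording a [raw_recording()].
#' @param n_components number of components to extract (default: one per
#'   channel). Note that zeroing `k` components leaves the cleaned data with
#'   rank `n_channels - k`, so a second pass over cleaned data must request
#'   correspondingly fewer components.
#' @param threshold absolute correlation above which a component is flagged
#'   as ocular.
#' @param frontal_channels channels averaged into the surrogate EOG.
#' @param seed seed for the ICA random initialization.
#' @return list with `recording` (cleaned copy) and `report`: a data.frame
#'   with one row per component (`component`, `score` = correlation with the
#'   surrogate EOG, `flagged`), plus the ICA iteration count as an attribute.
#' @export
remove_eog <- function(recording, n_components = nrow(recording$data),
                       threshold = 0.7,
                       frontal_channels = c("FP1", "FP2"), seed = 1) {
  stopifnot(inherits(recording, "raw_recording"))
  n_ch <- nrow(recording$data)
  if (n_components > n_ch) {
    stop("n_components (", n_components, ") exceeds channel count (", n_ch, ")")
  }
  if (ncol(recording$data) < 10 * n_ch) {
    stop("too few samples for a stable decomposition (need >> channels)")
  }
  frontal_channels <- intersect(frontal_channels, recording$layout$name)
  if (length(frontal_channels) == 0) {
    # fall back on the most anterior channels in the montage
    frontal_channels <- recording$layout$name[order(-recording$layout$y)][1:2]
  }
  fidx <- channel_index(recording, frontal_channels)
  surrogate <- colMeans(recording$data[fidx, , drop = FALSE])
  lp <- signal::butter(2, c(0.5, 4) / (recording$fs / 2), type = "pass")
  surrogate <- filtfilt_fast(lp$b, lp$a, surrogate,
                             min(length(surrogate) - 1,
                                 round(4 * recording$fs)))

  ica <- fast_ica(recording$data, n_components, seed = seed)
  scores <- as.numeric(stats::cor(t(ica$S), surrogate))
  flagged <- which(abs(scores) > threshold)
  S <- ica$S
  if (length(flagged) > 0) S[flagged, ] <- 0
  recording$data <- ica$mixing %*% S + ica$means
  report <- data.frame(component = seq_len(n_components), score = scores,
                       flagged = seq_len(n_components) %in% flagged)
  attr(report, "ica_iterations") <- ica$iterations
  list(recording = recording, report = report)
}

#' Discard baselines and trim trials to the analysis span
#'
#' Removes the pre-trial baseline spans (and any other unannotated data,
#' including the resting baseline) and keeps only the last
#' `analysis_seconds` of each annotated trial, so that all retained trial
#' blocks have identical length. Baseline "removal" here means discarding
#' the span, not mean-subtraction.
#'
#' @param recording a [raw_recording()] with trial annotations.
#' @param pre_trial_s required pre-trial baseline span (seconds); every
#'   trial must be preceded by at least this much recorded data.
#' @param analysis_seconds span retained from the end of each trial.
#' @return a new recording containing only the concatenated retained spans,
#'   with annotations re-anchored.
#' @export
strip_baseline <- function(recording, pre_trial_s = 5, analysis_seconds = 50) {
  stopifnot(inherits(recording, "raw_recording"))
  ann <- recording$annotations
  if (nrow(ann) == 0) stop("recording has no trial annotations")
  fs <- recording$fs
  short <- which(ann$duration_s < analysis_seconds - 1e-9)
  if (length(short) > 0) {
    stop("trial(s) shorter than the ", analysis_seconds,
         " s analysis span: trial_index ",
         paste(ann$trial_index[short], collapse = ", "))
  }
  if (any(ann$onset_s < pre_trial_s - 1e-9)) {
    bad <- ann$trial_index[ann$onset_s < pre_trial_s - 1e-9]
    stop("trial(s) lack a ", pre_trial_s, " s pre-trial span: trial_index ",
         paste(bad, collapse = ", "))
  }
  keep_n <- round(analysis_seconds * fs)
  pieces <- vector("list", nrow(ann))
  new_ann <- ann
  for (i in seq_len(nrow(ann))) {
    end <- round((ann$onset_s[i] + ann$duration_s[i]) * fs)
    idx <- (end - keep_n + 1L):end
    pieces[[i]] <- recording$data[, idx, drop = FALSE]
    new_ann$onset_s[i] <- (i - 1) * analysis_seconds
    new_ann$duration_s[i] <- analysis_seconds
  }
  raw_recording(do.call(cbind, pieces), fs, recording$layout, new_ann,
                subject_id = recording$subject_id)
}

#' Cut a recording into fixed-length overlapping labeled epochs
#'
#' Slides a `window_s` window with fractional `overlap` across each
#' annotated trial; every epoch inherits the trial's labels. Windows never
#' cross trial boundaries. A trial of length `L` seconds yields
#' `floor((L - window_s) / (window_s * (1 - overlap))) + 1` epochs.
#'
#' @param recording a [raw_recording()] with trial annotations.
#' @param window_s epoch length in seconds (default 2).
#' @param overlap fractional overlap between consecutive windows in
#'   `[0, 1)` (default 0.5).
#' @return an `epoch_set`: list with `data` (channels x samples x epochs
#'   array), `meta` (one row per epoch: subject_id, trial_index, clip_id,
#'   emotion, paradigm, epoch_index), `fs` and `layout`.
#' @export
segment_epochs <- function(recording, window_s = 2, overlap = 0.5) {
  stopifnot(inherits(recording, "raw_recording"))
  if (!(overlap >= 0 && overlap < 1)) stop("overlap must be in [0, 1)")
  ann <- recording$annotations
  if (nrow(ann) == 0) stop("recording has no trial annotations")
  if (any(ann$duration_s < window_s - 1e-9)) {
    stop("window (", window_s, " s) longer than trial(s): trial_index ",
         paste(ann$trial_index[ann$duration_s < window_s - 1e-9],
               collapse = ", "))
  }
  fs <- recording$fs
  win_n <- round(window_s * fs)
  hop_n <- round(window_s * (1 - overlap) * fs)
  counts <- floor((ann$duration_s - window_s) / (window_s * (1 - overlap)) + 1e-9) + 1L
  total <- sum(counts)
  data <- array(0, dim = c(nrow(recording$data), win_n, total))
  meta <- vector("list", nrow(ann))
  e <- 0L
  for (i in seq_len(nrow(ann))) {
    start0 <- round(ann$onset_s[i] * fs)
    for (j in seq_len(counts[i])) {
      idx <- (start0 + (j - 1L) * hop_n + 1L):(start0 + (j - 1L) * hop_n + win_n)
      e <- e + 1L
      data[, , e] <- recording$data[, idx, drop = FALSE]
    }
    meta[[i]] <- data.frame(subject_id = recording$subject_id,
                            trial_index = ann$trial_index[i],
                            clip_id = ann$clip_id[i],
                            emotion = ann$emotion[i],
                            paradigm = ann$paradigm[i],
                            epoch_index = seq_len(counts[i]),
                            stringsAsFactors = FALSE)
  }
  structure(list(data = data, meta = do.call(rbind, meta), fs = fs,
                 layout = recording$layout),
            class = "epoch_set")
}
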