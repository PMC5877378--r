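#' Spectral configuration for DE feature extraction
#'
#' @param stft_window STFT window length in samples (default 128).
#' @param stft_overlap fractional overlap between STFT frames (default 0.5).
#' @param taper taper function name; `"hamming"` or `"hann"`.
#' @param bands named list of `(low, high]` band ranges in Hz
#'   (default [eeg_bands()]).
#' @param epsilon floor applied to a band power or D_t of exactly zero
#'   before taking the log; such values are flagged.
#' @return a `spectral_config` list.
#' @export
spectral_config <- function(stft_window = 128, stft_overlap = 0.5,
                            taper = c("hamming", "hann"),
                            bands = eeg_bands(), epsilon = 1e-30) {
  taper <- match.arg(taper)
  edges <- unlist(bands)
  if (any(vapply(bands, function(b) b[1] >= b[2], logical(1)))) {
    stop("band edges must be strictly increasing")
  }
  structure(list(stft_window = stft_window, stft_overlap = stft_overlap,
                 taper = taper, bands = bands, epsilon = epsilon),
            class = "spectral_config")
}

taper_window <- function(name, n) {
  k <- seq_len(n) - 1
  switch(name,
         hamming = 0.54 - 0.46 * cos(2 * pi * k / (n - 1)),
         hann = 0.5 - 0.5 * cos(2 * pi * k / (n - 1)),
         stop("unknown taper: ", name))
}

#' Short-time Fourier transform power (spectrogram)
#'
#' Tapered, 50%-overlapping (by default) frame decomposition of a
#' single-channel epoch; frames that would overrun the epoch are dropped
#' (no padding). Power is the squared magnitude of the one-sided DFT.
#'
#' @param x numeric vector, one channel of one epoch.
#' @param fs sampling rate, Hz.
#' @param config a [spectral_config()].
#' @return list with `power` (frames x bins matrix), `freqs` (Hz per bin)
#'   and `times` (frame-center times, s).
#' @export
stft_power <- function(x, fs, config = spectral_config()) {
  w <- config$stft_window
  n <- length(x)
  if (n < w) stop("epoch (", n, " samples) shorter than STFT window (", w, ")")
  hop <- round(w * (1 - config$stft_overlap))
  n_frames <- floor((n - w) / hop) + 1
  win <- taper_window(config$taper, w)
  frames <- vapply(seq_len(n_frames),
                   function(i) x[((i - 1) * hop + 1):((i - 1) * hop + w)] * win,
                   numeric(w))
  spec <- stats::mvfft(frames)
  nb <- w %/% 2 + 1
  power <- t(Mod(spec[1:nb, , drop = FALSE])^2)
  list(power = power, freqs = (0:(nb - 1)) * fs / w,
       times = ((seq_len(n_frames) - 1) * hop + w / 2) / fs)
}

band_bins <- function(freqs, band) {
  which(freqs > band[1] & freqs <= band[2])
}

#' Differential entropy of a frequency band
#'
#' DE of a band over an epoch: the natural log of the band power
#' (spectrogram values summed over the band's bins) averaged over STFT
#' frames. A signal scaled by `a` shifts the DE by exactly `log(a^2)`.
#'
#' @param spec result of [stft_power()].
#' @param band `c(low, high)` in Hz, interpreted as `(low, high]`;
#'   must lie below the Nyquist frequency.
#' @param epsilon floor for zero band power (the result is then flagged via
#'   the `"floored"` attribute).
#' @return single DE value in nats (log power units).
#' @export
band_de <- function(spec, band, epsilon = 1e-30) {
  if (band[2] > max(spec$freqs)) {
    stop("band (", band[1], "-", band[2], " Hz) exceeds the spectral range")
  }
  bins <- band_bins(spec$freqs, band)
  if (length(bins) == 0) stop("no STFT bins fall inside the band")
  p <- mean(rowSums(spec$power[, bins, drop = FALSE]))
  flo <- p <= 0
  de <- log(max(p, epsilon))
  if (flo) attr(de, "floored") <- TRUE
  de
}

#' Empirical mode decomposition of a single-channel signal
#'
#' Adaptive sifting into intrinsic mode functions (IMFs) ordered fastest to
#' slowest, plus a residue. Envelopes are cubic splines through the local
#' extrema with two extrema mirrored across each boundary; sifting stops
#' when the normalized envelope mean is below `tol` at >= 95% of samples
#' (hard cap `max_sift` sifts), and the decomposition stops at `max_imf`
#' modes or when the residue has fewer than 4 extrema. By construction the
#' IMFs and residue sum back to the input to floating-point accuracy.
#'
#' @param x numeric vector (finite values).
#' @param max_imf maximum number of IMFs to extract.
#' @param tol sifting stop tolerance on the normalized envelope mean.
#' @param max_sift hard cap on sifting iterations per IMF.
#' @return an `imf_set`: list with `imfs` (samples x n_imf matrix, possibly
#'   zero columns), `residue`, and `n_sifts` per IMF.
#' @export
emd <- function(x, max_imf = 8, tol = 0.05, max_sift = 100) {
  if (!is.numeric(x)) stop("input must be numeric")
  res <- emd_cpp(as.numeric(x), max_imf = max_imf, tol = tol,
                 max_sift = max_sift)
  structure(res, class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMFs over %d samples (sift counts: %s)\n",
              ncol(x$imfs), length(x$residue),
              paste(x$n_sifts, collapse = ", ")))
  invisible(x)
}

#' Log mean absolute first difference of a series
#'
#' `D_t = mean(|x[n+1] - x[n]|)`; the feature used on IMF1 is `log(D_t)`.
#' A constant series (D_t = 0) is floored at `epsilon` and flagged.
#'
#' @param x numeric series of length >= 2.
#' @param epsilon floor for a zero D_t.
#' @return `log(D_t)`, with a `"floored"` attribute when the floor fired.
#' @export
dt_feature <- function(x, epsilon = 1e-30) {
  if (length(x) < 2) stop("series must have at least 2 samples")
  dt <- mean(abs(diff(x)))
  flo <- dt <= 0
  v <- log(max(dt, epsilon))
  if (flo) attr(v, "floored") <- TRUE
  v
}

#' Feature names for a montage
#'
#' Fixed column order of the feature matrix: channels in layout order, and
#' within each channel the five band DEs (delta, theta, alpha, beta, gamma)
#' followed by the EMD D_t feature. For the 61-channel montage this gives
#' 366 features (305 DE + 61 EMD).
#'
#' @param layout a layout data.frame (see [channel_layout()]).
#' @param bands band list (names only are used).
#' @return character vector like `"T7_DE_gamma"`, `"T7_EMD_Dt"`.
#' @export
feature_names <- function(layout, bands = eeg_bands()) {
  fams <- c(paste0("DE_", names(bands)), "EMD_Dt")
  as.vector(t(outer(layout$name, fams, paste, sep = "_")))
}

#' Electrode / family decomposition of feature names
#'
#' @param names feature names as produced by [feature_names()].
#' @return data.frame with columns `feature`, `electrode`, `family`.
#' @export
feature_info <- function(names) {
  data.frame(feature = names,
             electrode = sub("_.*$", "", names),
             family = sub("^[^_]*_", "", names),
             stringsAsFactors = FALSE)
}

#' Extract the DE + EMD feature matrix from an epoch set
#'
#' Per epoch and channel: differential entropy of the five bands from the
#' STFT spectrogram, and the log mean absolute first difference of IMF1
#' from empirical mode decomposition — 6 features per channel, 366 for the
#' full 61-channel montage. Channels are processed independently; the
#' computation is deterministic.
#'
#' @param epochs an `epoch_set` from [segment_epochs()].
#' @param config a [spectral_config()].
#' @param chunk internal batching size (epochs per EMD batch).
#' @return a `feature_matrix`: list with `X` (epochs x features numeric
#'   matrix with feature-name columns), `meta` (the epoch metadata), and
#'   `layout`. The attribute `"n_floored"` on `X` counts log-floor events.
#' @export
extract_features <- function(epochs, config = spectral_config(), chunk = 64) {
  stopifnot(inherits(epochs, "epoch_set"))
  n_ch <- dim(epochs$data)[1]
  win_n <- dim(epochs$data)[2]
  n_ep <- dim(epochs$data)[3]
  w <- config$stft_window
  if (win_n < w) {
    stop("epoch length (", win_n, ") shorter than STFT window (", w, ")")
  }
  hop <- round(w * (1 - config$stft_overlap))
  n_frames <- floor((win_n - w) / hop) + 1
  win <- taper_window(config$taper, w)
  nb <- w %/% 2 + 1
  freqs <- (0:(nb - 1)) * epochs$fs / w
  bands <- config$bands
  nbands <- length(bands)
  bin_band <- rep(0L, nb)  # 0 = outside every band
  for (b in seq_along(bands)) bin_band[band_bins(freqs, bands[[b]])] <- b
  if (any(vapply(seq_along(bands),
                 function(b) !any(bin_band == b), logical(1)))) {
    stop("band(s) with no STFT bins at this window/sampling rate: ",
         paste(names(bands)[vapply(seq_along(bands),
               function(b) !any(bin_band == b), logical(1))], collapse = ", "))
  }

  # accumulate band power summed over frames, per channel x epoch
  acc <- array(0, dim = c(nbands, n_ch, n_ep))
  grp <- bin_band + 1L   # rowsum group (1 = discard)
  for (f in seq_len(n_frames)) {
    idx <- ((f - 1) * hop + 1):((f - 1) * hop + w)
    sl <- epochs$data[, idx, , drop = FALSE]            # ch x w x ep
    m <- matrix(aperm(sl, c(2, 1, 3)), nrow = w) * win  # w x (ch*ep)
    p <- Mod(stats::mvfft(m)[1:nb, , drop = FALSE])^2
    bp <- rowsum(p, grp)                                 # groups x (ch*ep)
    keep <- match(2:(nbands + 1), as.integer(rownames(bp)))
    acc <- acc + array(bp[keep, , drop = FALSE], dim = c(nbands, n_ch, n_ep))
  }
  mean_bp <- acc / n_frames
  n_floored <- sum(mean_bp <= 0)
  de <- log(pmax(mean_bp, config$epsilon))               # bands x ch x ep

  # EMD D_t of IMF1, batched over epochs
  dt <- matrix(0, n_ch, n_ep)
  for (s in seq(1, n_ep, by = chunk)) {
    e <- min(s + chunk - 1, n_ep)
    m <- matrix(aperm(epochs$data[, , s:e, drop = FALSE], c(2, 1, 3)),
                nrow = win_n)
    dt[, s:e] <- imf1_dt_batch(m)
  }
  n_floored <- n_floored + sum(dt <= 0)
  logdt <- log(pmax(dt, config$epsilon))                 # ch x ep

  # interleave into channel-major blocks: 5 DEs then EMD_Dt per channel
  X <- matrix(0, n_ep, n_ch * (nbands + 1))
  for (ch in seq_len(n_ch)) {
    cols <- (ch - 1) * (nbands + 1) + seq_len(nbands)
    X[, cols] <- t(de[, ch, ])
    X[, (ch - 1) * (nbands + 1) + nbands + 1] <- logdt[ch, ]
  }
  colnames(X) <- feature_names(epochs$layout, bands)
  attr(X, "n_floored") <- n_floored
  structure(list(X = X, meta = epochs$meta, layout = epochs$layout),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d epochs x %d features (%d subjects)\n",
              nrow(x$X), ncol(x$X), length(unique(x$meta$subject_id))))
  invisible(x)
}

#' Filter a feature matrix by epoch metadata
#'
#' @param fm a `feature_matrix`.
#' @param subject_id,paradigm,emotion optional filters.
#' @return the filtered `feature_matrix`.
#' @export
filter_epochs <- function(fm, subject_id = NULL, paradigm = NULL,
                          emotion = NULL) {
  keep <- rep(TRUE, nrow(fm$meta))
  if (!is.null(subject_id)) keep <- keep & fm$meta$subject_id %in% subject_id
  if (!is.null(paradigm)) keep <- keep & fm$meta$paradigm %in% paradigm
  if (!is.null(emotion)) keep <- keep & fm$meta$emotion %in% emotion
  fm$X <- fm$X[keep, , drop = FALSE]
  fm$meta <- fm$meta[keep, , drop = FALSE]
  rownames(fm$meta) <- NULL
  fm
}

#' Bind feature matrices from several subjects
#' @param ... `feature_matrix` objects over the same layout.
#' @return the combined `feature_matrix`.
#' @export
bind_features <- function(...) {
  fms <- list(...)
  if (length(fms) == 1 && is.list(fms[[1]]) &&
      !inherits(fms[[1]], "feature_matrix")) fms <- fms[[1]]
  stopifnot(length(fms) >= 1)
  nm <- colnames(fms[[1]]$X)
  for (f in fms) {
    if (!identical(colnames(f$X), nm)) stop("feature columns differ")
  }
  structure(list(X = do.call(rbind, lapply(fms, `[[`, "X")),
                 meta = do.call(rbind, lapply(fms, `[[`, "meta")),
                 layout = fms[[1]]$layout),
            class = "feature_matrix")
}

#' Write a feature matrix to CSV
#'
#' One row per epoch: the metadata columns followed by the named features.
#' @param fm a `feature_matrix`.
#' @param path output file.
#' @export
write_features_csv <- function(fm, path) {
  df <- cbind(fm$meta, as.data.frame(fm$X, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
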